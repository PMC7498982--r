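# End-to-end analysis orchestration -------------------------------------
#
# Wires extraction output (or a synthetic cohort) through age adjustment,
# standardization, PLS1, component association and the permutation-validated
# leave-one-out prediction, for a single metric or for FA combined with one
# companion metric (the four variants: FA; FA+MD; FA+MB_count;
# FA+MB_volume). Microbleed metrics are z-scored but never age-adjusted.

AGE_ADJUSTED_METRICS <- c("FA", "MD")
KNOWN_METRICS <- c("FA", "MD", "MB_count", "MB_volume")

#' Configuration of a full analysis run
#'
#' @param metric_set Character vector: one metric, or `"FA"` plus exactly
#'   one companion from `MD`, `MB_count`, `MB_volume`.
#' @param fa_threshold Strict FA threshold for extraction (default 0.3).
#' @param erode Apply 1-voxel erosion in extraction (default `TRUE`).
#' @param n_components PLS components used throughout (default 3).
#' @param variance_threshold Percent threshold for [choose_components()]
#'   (default 80).
#' @param alpha Nominal significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor for component tests (default 3;
#'   `alpha / n_comparisons` reproduces the 0.017 corrected level).
#' @param B Permutations for the prediction test (default 10000).
#' @param impute_pta_days Outcome imputed for subjects with missing PTA,
#'   e.g. deceased before emergence (default 400 days).
#' @param adjustment `"slope"` or `"residual"`, see
#'   [apply_age_adjustment()].
#' @param seed Integer seed for the permutation draw.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(metric_set = "FA", fa_threshold = 0.3,
                            erode = TRUE, n_components = 3,
                            variance_threshold = 80, alpha = 0.05,
                            n_comparisons = 3, B = 10000,
                            impute_pta_days = 400,
                            adjustment = c("slope", "residual"),
                            seed = NULL) {
  adjustment <- match.arg(adjustment)
  if (!all(metric_set %in% KNOWN_METRICS))
    stop_invariant("unknown metric(s): ",
                   paste(setdiff(metric_set, KNOWN_METRICS), collapse = ", "))
  if (length(metric_set) > 2L)
    stop_invariant("metric_set pairs FA with at most one companion metric")
  if (length(metric_set) == 2L &&
      !("FA" %in% metric_set))
    stop_invariant("combined runs must include FA as the first block")
  if (length(metric_set) == 2L)
    metric_set <- c("FA", setdiff(metric_set, "FA"))
  if (alpha <= 0 || alpha >= 1 || n_comparisons < 1)
    stop_invariant("alpha must be in (0,1) and n_comparisons >= 1")
  structure(list(metric_set = metric_set, fa_threshold = fa_threshold,
                 erode = erode, n_components = as.integer(n_components),
                 variance_threshold = variance_threshold, alpha = alpha,
                 n_comparisons = as.integer(n_comparisons),
                 alpha_corrected = alpha / n_comparisons,
                 B = as.integer(B), impute_pta_days = impute_pta_days,
                 adjustment = adjustment,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "analysis_config")
}

# pull patient/control blocks out of a cohort-like object
split_cohort <- function(cohort) {
  subjects <- cohort$subjects
  stopifnot(all(c("id", "group", "age", "pta_days") %in% names(subjects)))
  list(subjects = subjects,
       is_patient = subjects$group == "patient",
       metrics = cohort$metrics)
}

#' Run the complete pattern-analysis pipeline on a cohort
#'
#' Steps: impute missing patient PTA with `config$impute_pta_days`;
#' estimate linear age trends per (region, metric) in the controls and
#' remove them from patient FA/MD (microbleed metrics are only z-scored);
#' z-score every predictor column and the outcome across patients; fit
#' PLS1; test the first three components against PTA by one-tailed Spearman
#' correlation at the corrected alpha; and validate prediction by
#' leave-one-out cross-validation against a permutation null.
#'
#' @param cohort A `pta_cohort` (or any list with `subjects` and `metrics`
#'   of the same shape, e.g. from [read_cohort_dir()]).
#' @param config An [analysis_config()].
#' @return List of class `pta_analysis`: `fit` (the `pls1_fit`),
#'   `associations`, `loocv` (the `loocv_result`), `X` (adjusted,
#'   unstandardized patient predictors), `y` (patient PTA in days, imputed
#'   where missing), `trends`, and `provenance` (package version, config
#'   hash, seed, imputed subject ids, sign/tail conventions).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' res <- run_analysis(coh, analysis_config(metric_set = "FA", B = 200,
#'                                          seed = 7))
#' res$loocv$observed_rho
run_analysis <- function(cohort, config = analysis_config()) {
  if (!inherits(config, "analysis_config"))
    stop_invariant("config must be created with analysis_config()")
  parts <- split_cohort(cohort)
  pat <- parts$is_patient
  subjects <- parts$subjects

  y <- subjects$pta_days[pat]
  imputed <- subjects$id[pat][is.na(y)]
  y[is.na(y)] <- config$impute_pta_days

  hc_ages <- subjects$age[!pat]
  pat_ages <- subjects$age[pat]

  blocks <- list()
  trends_all <- list()
  for (m in config$metric_set) {
    x <- parts$metrics[[m]]
    if (is.null(x))
      stop_invariant("stage adjustment: metric ", m, " missing from cohort")
    xp <- x[pat, , drop = FALSE]
    if (m %in% AGE_ADJUSTED_METRICS) {
      tr <- fit_age_trends(x[!pat, , drop = FALSE], hc_ages, metric_name = m)
      xp <- apply_age_adjustment(xp, pat_ages, tr, method = config$adjustment,
                                 metric_name = m)
      trends_all[[m]] <- tr
    }
    colnames(xp) <- paste(m, colnames(xp), sep = "_")
    blocks[[m]] <- xp
  }
  X <- do.call(cbind, blocks)

  zx <- zscore_columns(X)
  zy <- zscore_columns(cbind(pta = y))
  fit <- fit_pls1(zx$x, drop(zy$x), n_components = config$n_components,
                  center = zx$center, scale = zx$scale)
  associations <- correlate_components(
    fit, y, n_test = min(3L, config$n_components),
    alpha_corrected = config$alpha_corrected)
  loocv <- permutation_test(X, y, n_components = config$n_components,
                            B = config$B, seed = config$seed)

  trends <- if (length(trends_all)) do.call(rbind, trends_all) else NULL
  structure(list(
    fit = fit, associations = associations, loocv = loocv,
    X = X, y = y, trends = trends,
    provenance = list(
      package_version = as.character(packageVersion("ptapls")),
      config = config,
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      imputed_subjects = imputed,
      sign_convention = "sum of predictor loadings <= 0 per component",
      association_tail = "positive",
      prediction_tail = "positive")),
    class = "pta_analysis")
}

#' @export
print.pta_analysis <- function(x, ...) {
  cfg <- x$provenance$config
  cat("PTA pattern analysis:", paste(cfg$metric_set, collapse = " + "),
      "(", length(x$y), "patients )\n")
  cat("Cumulative % predictor variance:",
      paste(sprintf("%.0f", x$fit$pct_var_x), collapse = "/"), "\n")
  for (i in seq_len(nrow(x$associations)))
    cat(sprintf("  component %d: rho = %.2f, one-tailed p = %.3f%s\n",
                x$associations$component[i], x$associations$rho[i],
                x$associations$p[i],
                if (x$associations$significant[i]) " *" else ""))
  cat(sprintf("LOOCV: rho = %.2f, permutation p = %.3f (B = %d)\n",
              x$loocv$observed_rho, x$loocv$p, x$loocv$B))
  invisible(x)
}

#' Pick the shared component count by the joint variance rule
#'
#' Fits a full-rank single-metric PLS1 for each metric and returns the
#' smallest component count whose cumulative predictor variance strictly
#' exceeds the threshold for every metric.
#'
#' @param cohort A `pta_cohort`-like object.
#' @param metrics Metrics to cover (default all four).
#' @param config An [analysis_config()] supplying threshold, adjustment and
#'   imputation settings.
#' @return List with `n_components` and the per-metric `pct_var_x` table.
#' @export
choose_components <- function(cohort, metrics = KNOWN_METRICS,
                              config = analysis_config()) {
  parts <- split_cohort(cohort)
  pat <- parts$is_patient
  subjects <- parts$subjects
  y <- subjects$pta_days[pat]
  y[is.na(y)] <- config$impute_pta_days
  tabs <- list()
  for (m in metrics) {
    x <- parts$metrics[[m]]
    if (is.null(x)) stop_invariant("metric ", m, " missing from cohort")
    xp <- x[pat, , drop = FALSE]
    if (m %in% AGE_ADJUSTED_METRICS) {
      tr <- fit_age_trends(x[!pat, , drop = FALSE], subjects$age[!pat],
                           metric_name = m)
      xp <- apply_age_adjustment(xp, subjects$age[pat], tr,
                                 method = config$adjustment, metric_name = m)
    }
    zx <- zscore_columns(xp)
    zy <- zscore_columns(cbind(y))
    rk <- qr(zx$x)$rank
    fit <- fit_pls1(zx$x, drop(zy$x), n_components = rk)
    tabs[[m]] <- fit$pct_var_x
  }
  list(n_components = select_n_components(tabs,
                                          threshold = config$variance_threshold),
       pct_var_x = tabs)
}

#' Read a cohort written by [write_cohort()] back from CSV
#'
#' @param dir Directory with `subjects.csv` and `metric_<name>.csv` files.
#' @return List with `subjects` and `metrics`, usable by [run_analysis()].
#' @export
read_cohort_dir <- function(dir) {
  subjects <- read.csv(file.path(dir, "subjects.csv"),
                       stringsAsFactors = FALSE)
  files <- list.files(dir, pattern = "^metric_.*\\.csv$", full.names = TRUE)
  metrics <- list()
  for (f in files) {
    long <- read.csv(f, stringsAsFactors = FALSE)
    m <- unique(long$metric)
    wide <- matrix(NA_real_, nrow(subjects), 5,
                   dimnames = list(subjects$id, pta_regions()))
    for (k in seq_len(nrow(long)))
      wide[long$subject[k], long$region[k]] <- long$value[k]
    metrics[[m]] <- wide
  }
  list(subjects = subjects, metrics = metrics)
}

#' Summarize clinical variables the way cohort tables print them
#'
#' Per numeric variable: n used (missing excluded), mean and sample SD
#' (n-1) rounded to whole numbers, median, and min-max range. SD is
#' reported as missing for a single observation.
#'
#' @param subjects Data frame of clinical variables.
#' @param variables Columns to summarize (default: all numeric columns).
#' @return Data frame with one row per variable.
#' @export
#' @examples
#' path <- system.file("extdata", "tbi_patient_clinical.csv",
#'                     package = "ptapls")
#' summarize_clinical(read.csv(path))
summarize_clinical <- function(subjects,
                               variables = names(subjects)[
                                 vapply(subjects, is.numeric, logical(1))]) {
  if (!nrow(subjects)) stop_invariant("empty subject table")
  rows <- lapply(variables, function(v) {
    x <- subjects[[v]]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(variable = v, n = 0L, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, min = NA_real_, max = NA_real_))
    data.frame(variable = v, n = length(x),
               mean = round(mean(x)),
               sd = if (length(x) > 1L) round(sd(x)) else NA_real_,
               median = as.numeric(median(x)),
               min = as.numeric(min(x)), max = as.numeric(max(x)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Age-corrected Spearman correlations of clinical covariates with outcome
#'
#' Optional report in the style of clinical-covariate tables: partial
#' Spearman correlation via rank residualization (ranks of covariate and
#' outcome are each residualized on the rank of age by least squares, then
#' Pearson-correlated), with a two-tailed t-approximation p on n - 3
#' degrees of freedom. The exact age correction used in published tables
#' is rarely stated; this declared method is a reasonable default, not a
#' reproduction claim.
#'
#' @param subjects Data frame with the covariates, outcome and age.
#' @param covariates Covariate column names.
#' @param outcome Outcome column (default `"pta_days"`).
#' @param age Age column (default `"age"`).
#' @return Data frame with `covariate`, `rho`, `p`, `n`.
#' @export
clinical_outcome_correlations <- function(subjects, covariates,
                                          outcome = "pta_days", age = "age") {
  rows <- lapply(covariates, function(v) {
    keep <- stats::complete.cases(subjects[, c(v, outcome, age)])
    x <- subjects[[v]][keep]; y <- subjects[[outcome]][keep]
    a <- subjects[[age]][keep]
    n <- length(x)
    if (n < 5L) stop_invariant("need >= 5 complete cases for ", v)
    rx <- stats::resid(lm(rank(x) ~ rank(a)))
    ry <- stats::resid(lm(rank(y) ~ rank(a)))
    rho <- cor(rx, ry)
    tstat <- rho * sqrt((n - 3) / max(1 - rho^2, .Machine$double.eps))
    data.frame(covariate = v, rho = rho,
               p = 2 * pt(abs(tstat), df = n - 3, lower.tail = FALSE), n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
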