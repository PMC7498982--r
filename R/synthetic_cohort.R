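# Synthetic cohort generation -------------------------------------------
#
# Emulates the statistical structure the downstream analysis assumes: a
# small severe-TBI group and a larger healthy-control group, regional
# DTI-type metrics with linear age trends, and two latent damage severities
# per patient (a global pattern expressed uniformly across regions and a
# deep-vs-superficial pattern with opposite sign in CC/BS) that jointly
# drive the duration of post-traumatic amnesia.

#' Per-metric generative parameters for a synthetic cohort
#'
#' @param baselines Named numeric vector of length 5 (regions in
#'   [pta_regions()] order): metric mean at age 0 of the age trend.
#' @param age_slopes Named numeric vector of length 5: metric change per
#'   year of age, shared by patients and controls.
#' @param effect_global Metric units per SD of the global damage severity.
#'   Negative for FA (damage lowers anisotropy), positive for MD.
#' @param effect_deep Metric units per SD of the deep-vs-superficial
#'   severity, applied along the deep pattern vector.
#' @param noise_sd Residual between-subject SD in metric units.
#' @param integer_valued Round generated values to integers (counts).
#' @param nonnegative Clip generated values at zero.
#' @return A list of class `metric_spec`.
#' @export
metric_spec <- function(baselines, age_slopes, effect_global, effect_deep,
                        noise_sd, integer_valued = FALSE, nonnegative = FALSE) {
  regions <- pta_regions()
  baselines <- check_region_vector(baselines, "baselines")
  age_slopes <- check_region_vector(age_slopes, "age_slopes")
  stopifnot(length(effect_global) == 1L, length(effect_deep) == 1L,
            length(noise_sd) == 1L, noise_sd >= 0)
  structure(list(baselines = baselines, age_slopes = age_slopes,
                 effect_global = effect_global, effect_deep = effect_deep,
                 noise_sd = noise_sd, integer_valued = integer_valued,
                 nonnegative = nonnegative),
            class = "metric_spec")
}

check_region_vector <- function(x, what) {
  regions <- pta_regions()
  if (length(x) != 5L)
    stop_invariant(what, " must have one entry per region (5)")
  if (is.null(names(x))) names(x) <- regions
  if (!identical(sort(names(x)), sort(regions)))
    stop_invariant(what, " must be named with the five region codes")
  x[regions]
}

default_metric_specs <- function() {
  # FA: unitless; WM regions ~0.4-0.55, BT (grey matter) lower; mild
  # age-related decline. MD in mm^2/s (~7.5e-4), rising with age and damage.
  # Microbleed count/volume: no age trend, damage raises both.
  list(
    FA = metric_spec(
      baselines = c(FT = 0.45, PO = 0.46, CC = 0.58, BS = 0.52, BT = 0.33),
      age_slopes = c(FT = -8e-4, PO = -8e-4, CC = -9e-4, BS = -6e-4, BT = -4e-4),
      effect_global = -0.08, effect_deep = -0.06, noise_sd = 0.008),
    MD = metric_spec(
      baselines = c(FT = 7.6e-4, PO = 7.5e-4, CC = 7.2e-4, BS = 7.4e-4,
                    BT = 8.0e-4),
      age_slopes = c(FT = 1.5e-6, PO = 1.5e-6, CC = 1.8e-6, BS = 1.0e-6,
                     BT = 1.2e-6),
      effect_global = 8e-5, effect_deep = 6e-5, noise_sd = 8e-6),
    MB_count = metric_spec(
      baselines = c(FT = 4, PO = 3, CC = 2, BS = 1, BT = 1),
      age_slopes = c(FT = 0, PO = 0, CC = 0, BS = 0, BT = 0),
      effect_global = 3, effect_deep = 2, noise_sd = 1,
      integer_valued = TRUE, nonnegative = TRUE),
    MB_volume = metric_spec(
      baselines = c(FT = 60, PO = 45, CC = 25, BS = 12, BT = 12),
      age_slopes = c(FT = 0, PO = 0, CC = 0, BS = 0, BT = 0),
      effect_global = 30, effect_deep = 20, noise_sd = 8,
      nonnegative = TRUE)
  )
}

#' Configuration of a synthetic TBI cohort
#'
#' Defaults describe the study design the pipeline targets: 14 patients and
#' 21 healthy controls, patient ages spanning 18-77 years, two unit-norm
#' spatial damage patterns (global: same sign in all five regions;
#' deep: CC and BS opposite in sign to FT, PO and BT), and a PTA duration
#' generated linearly from the two per-patient severities, clipped and
#' rounded to whole days.
#'
#' @param n_patients,n_controls Group sizes (each at least 5).
#' @param age_range Years, `c(min, max)`; ages are drawn uniformly.
#' @param metrics Named list of [metric_spec()] objects.
#' @param global_pattern,deep_pattern Unit-norm length-5 direction vectors
#'   of the two damage patterns over regions.
#' @param pta_coefs `c(intercept, per-SD-global, per-SD-deep)` in days.
#' @param pta_noise_sd Residual SD of PTA in days.
#' @param pta_bounds `c(min, max)` clip range in days.
#' @param seed Integer seed; required for generation.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 14, n_controls = 21,
                          age_range = c(18, 77),
                          metrics = default_metric_specs(),
                          global_pattern = rep(1, 5) / sqrt(5),
                          deep_pattern = c(1, 1, -1, -1, 1) / sqrt(5),
                          pta_coefs = c(190, 80, 60),
                          pta_noise_sd = 60,
                          pta_bounds = c(0, 450),
                          seed = NULL) {
  regions <- pta_regions()
  global_pattern <- check_region_vector(global_pattern, "global_pattern")
  deep_pattern <- check_region_vector(deep_pattern, "deep_pattern")
  if (n_patients < 5 || n_controls < 5)
    stop_invariant("group sizes must satisfy n_patients >= 5 and n_controls >= 5")
  if (length(age_range) != 2L || diff(age_range) <= 0)
    stop_invariant("age_range must be c(min, max) with min < max")
  if (abs(sqrt(sum(global_pattern^2)) - 1) > 1e-8)
    stop_invariant("global_pattern must have unit Euclidean norm")
  if (abs(sqrt(sum(deep_pattern^2)) - 1) > 1e-8)
    stop_invariant("deep_pattern must have unit Euclidean norm")
  if (length(unique(sign(global_pattern))) != 1L || any(global_pattern == 0))
    stop_invariant("global_pattern entries must all share one sign")
  deep <- regions %in% deep_regions()
  if (length(unique(sign(deep_pattern[deep]))) != 1L ||
      length(unique(sign(deep_pattern[!deep]))) != 1L ||
      sign(deep_pattern[["CC"]]) == sign(deep_pattern[["FT"]]))
    stop_invariant("deep_pattern must have CC and BS opposite in sign to FT, PO and BT")
  if (!length(metrics) || is.null(names(metrics)) ||
      !all(vapply(metrics, inherits, logical(1), "metric_spec")))
    stop_invariant("metrics must be a named list of metric_spec objects")
  if (length(pta_coefs) != 3L)
    stop_invariant("pta_coefs must be c(intercept, per-SD global, per-SD deep)")
  if (length(pta_bounds) != 2L || diff(pta_bounds) <= 0)
    stop_invariant("pta_bounds must be c(min, max) with min < max")
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 age_range = age_range, metrics = metrics,
                 global_pattern = global_pattern, deep_pattern = deep_pattern,
                 pta_coefs = pta_coefs, pta_noise_sd = pta_noise_sd,
                 pta_bounds = pta_bounds,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cohort_config")
}

# noiseless regional means implied by the generative formula; severities are
# zero for controls so the same expression covers both groups
noiseless_regional_means <- function(spec, config, ages, g, d) {
  n <- length(ages)
  base <- matrix(spec$baselines, n, 5, byrow = TRUE)
  trend <- outer(ages, spec$age_slopes)
  eff <- spec$effect_global * outer(g, config$global_pattern) +
    spec$effect_deep * outer(d, config$deep_pattern)
  out <- base + trend + eff
  colnames(out) <- pta_regions()
  out
}

noiseless_pta <- function(config, g, d) {
  config$pta_coefs[1] + config$pta_coefs[2] * g + config$pta_coefs[3] * d
}

#' Generate a synthetic cohort with retained ground truth
#'
#' Draws, in a fixed sub-stream order (ages, severities, metric noise in the
#' order the metrics are declared, PTA noise), a patient + control cohort
#' whose regional metrics follow
#' `baseline_r + slope_r * age + effect_global * g_i * global_r +
#' effect_deep * d_i * deep_r + noise`, with both severities `g_i`, `d_i`
#' standard normal for patients and exactly zero for controls. PTA is
#' linear in the severities, clipped to `pta_bounds` and rounded to whole
#' days; controls have no PTA.
#'
#' @param config A [cohort_config()]; `config$seed` must be set.
#' @return A list of class `pta_cohort` with elements `subjects` (data frame
#'   `id`, `group`, `age`, `pta_days`), `metrics` (named list of
#'   subject-by-region matrices), and `ground_truth` (severities, patterns,
#'   noiseless regional means and PTA, and the generating config).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1))
#' head(coh$subjects)
#' round(coh$metrics$FA[1:3, ], 3)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_invariant("config must be created with cohort_config()")
  if (is.null(config$seed))
    stop_invariant("config$seed must be an integer for reproducible generation")
  set.seed(config$seed)
  np <- config$n_patients; nc <- config$n_controls; n <- np + nc
  regions <- pta_regions()

  ages <- round(runif(n, config$age_range[1], config$age_range[2]), 1)
  g <- c(rnorm(np), rep(0, nc))
  d <- c(rnorm(np), rep(0, nc))

  metrics <- vector("list", length(config$metrics))
  names(metrics) <- names(config$metrics)
  true_means <- metrics
  ids <- c(sprintf("P%02d", seq_len(np)), sprintf("C%02d", seq_len(nc)))
  for (m in names(config$metrics)) {
    spec <- config$metrics[[m]]
    mu <- noiseless_regional_means(spec, config, ages, g, d)
    x <- mu + matrix(rnorm(n * 5, sd = spec$noise_sd), n, 5)
    if (spec$nonnegative) x <- pmax(x, 0)
    if (spec$integer_valued) x <- round(x)
    dimnames(x) <- list(ids, regions)
    dimnames(mu) <- list(ids, regions)
    metrics[[m]] <- x
    true_means[[m]] <- mu
  }

  pta_clean <- noiseless_pta(config, g[seq_len(np)], d[seq_len(np)])
  pta <- pta_clean + rnorm(np, sd = config$pta_noise_sd)
  pta <- round(pmin(pmax(pta, config$pta_bounds[1]), config$pta_bounds[2]))

  subjects <- data.frame(
    id = ids,
    group = rep(c("patient", "control"), c(np, nc)),
    age = ages,
    pta_days = c(pta, rep(NA_real_, nc)),
    stringsAsFactors = FALSE)

  structure(list(
    subjects = subjects,
    metrics = metrics,
    ground_truth = list(
      g = setNames(g, ids), d = setNames(d, ids),
      global_pattern = config$global_pattern,
      deep_pattern = config$deep_pattern,
      noiseless_means = true_means,
      noiseless_pta = setNames(pta_clean, ids[seq_len(np)]),
      config = config)),
    class = "pta_cohort")
}

#' Convert a cohort metric block to the long regional-metric table
#'
#' @param cohort A `pta_cohort`.
#' @param metrics Which metrics to include (default all).
#' @return Data frame with columns `subject`, `region`, `metric`, `value`.
#' @export
cohort_to_long <- function(cohort, metrics = names(cohort$metrics)) {
  out <- do.call(rbind, lapply(metrics, function(m) {
    x <- cohort$metrics[[m]]
    data.frame(subject = rep(rownames(x), times = ncol(x)),
               region = rep(colnames(x), each = nrow(x)),
               metric = m, value = as.vector(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a cohort to delimited text plus a ground-truth JSON
#'
#' Writes `subjects.csv`, one `metric_<name>.csv` per metric (long format)
#' and `ground_truth.json` into `dir`.
#'
#' @param cohort A `pta_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (m in names(cohort$metrics)) {
    long <- cohort_to_long(cohort, m)
    write.csv(long, file.path(dir, paste0("metric_", m, ".csv")),
              row.names = FALSE)
  }
  gt <- cohort$ground_truth
  gt$config$metrics <- lapply(gt$config$metrics, unclass)
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pta_cohort <- function(x, ...) {
  np <- sum(x$subjects$group == "patient")
  nc <- sum(x$subjects$group == "control")
  cat("Synthetic TBI cohort:", np, "patients,", nc, "controls\n")
  cat("Metrics:", paste(names(x$metrics), collapse = ", "), "\n")
  cat("Patient PTA (days): median",
      median(x$subjects$pta_days[x$subjects$group == "patient"]),
      "range", paste(range(x$subjects$pta_days, na.rm = TRUE), collapse = "-"),
      "\n")
  invisible(x)
}
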