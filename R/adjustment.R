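# Age adjustment and standardization ------------------------------------
#
# Diffusion metrics drift linearly with age in healthy tissue; the pipeline
# removes the trend estimated in the healthy-control group from patient
# values before pattern analysis, then z-scores every variable across
# subjects. Microbleed metrics are z-scored but not age-adjusted.

#' Fit per-(region, metric) linear age trends in healthy controls
#'
#' Ordinary least squares of metric value on age, fitted separately for
#' each region and metric, in the control group only.
#'
#' @param metrics Named list of subject-by-region matrices (control rows
#'   only), or a single matrix (then `metric_name` labels it).
#' @param ages Numeric vector of control ages, one per row.
#' @param metric_name Metric label used when `metrics` is a single matrix.
#' @return Data frame of class `age_trends` with columns `metric`,
#'   `region`, `slope`, `intercept`, `reference_age` (mean control age) and
#'   `n_controls`.
#' @export
fit_age_trends <- function(metrics, ages, metric_name = "metric") {
  if (is.matrix(metrics)) metrics <- setNames(list(metrics), metric_name)
  out <- list()
  for (m in names(metrics)) {
    x <- metrics[[m]]
    if (nrow(x) != length(ages))
      stop_invariant("ages must have one entry per control row (metric ", m, ")")
    for (r in colnames(x)) {
      v <- x[, r]
      ok <- is.finite(v) & is.finite(ages)
      if (sum(ok) < 3L)
        stop_invariant("need >= 3 controls with finite values for (",
                       r, ", ", m, ")")
      a <- ages[ok]
      if (sd(a) == 0)
        stop_invariant("degenerate control ages (all equal) for (",
                       r, ", ", m, ")")
      fit <- lm(v[ok] ~ a)
      out[[length(out) + 1L]] <- data.frame(
        metric = m, region = r,
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        reference_age = mean(a), n_controls = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("age_trends", "data.frame"))
}

#' Remove the healthy-control age trend from patient values
#'
#' Default (`method = "slope"`) subtracts `slope * (age - reference_age)`,
#' keeping values on their native scale (a patient at the control mean age
#' is unchanged). `method = "residual"` subtracts the full fitted control
#' line `intercept + slope * age` instead; the two differ only by a
#' per-column constant, which vanishes after z-scoring.
#'
#' @param metrics Named list of subject-by-region matrices (or one matrix).
#' @param ages Numeric vector of subject ages, one per row.
#' @param trends An `age_trends` object covering every (region, metric).
#' @param method `"slope"` (default) or `"residual"`.
#' @param metric_name Metric label when `metrics` is a single matrix.
#' @return Adjusted object of the same shape as `metrics`.
#' @export
apply_age_adjustment <- function(metrics, ages, trends,
                                 method = c("slope", "residual"),
                                 metric_name = "metric") {
  method <- match.arg(method)
  single <- is.matrix(metrics)
  if (single) metrics <- setNames(list(metrics), metric_name)
  for (m in names(metrics)) {
    x <- metrics[[m]]
    if (nrow(x) != length(ages))
      stop_invariant("ages must have one entry per row (metric ", m, ")")
    for (r in colnames(x)) {
      tr <- trends[trends$metric == m & trends$region == r, ]
      if (nrow(tr) != 1L)
        stop_invariant("no age trend available for (", r, ", ", m, ")")
      x[, r] <- if (method == "slope")
        x[, r] - tr$slope * (ages - tr$reference_age)
      else
        x[, r] - (tr$intercept + tr$slope * ages)
    }
    metrics[[m]] <- x
  }
  if (single) metrics[[1L]] else metrics
}

#' Standardize columns to mean 0 and unit sample SD
#'
#' Sample SD uses the n-1 denominator. The centering and scaling constants
#' are returned so held-out rows can be standardized with the same
#' constants (as leave-one-out prediction requires).
#'
#' @param x Numeric matrix (subjects by variables).
#' @return List with `x` (standardized matrix), `center` and `scale`.
#' @export
zscore_columns <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  bad <- which(!is.finite(scl) | scl == 0)
  if (length(bad))
    stop_invariant("zero-variance column(s): ",
                   paste(colnames(x)[bad], collapse = ", "))
  list(x = sweep(sweep(x, 2L, ctr), 2L, scl, `/`), center = ctr, scale = scl)
}
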