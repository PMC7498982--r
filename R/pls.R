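# PLS1 regression from first principles ---------------------------------
#
# Single-outcome partial least squares by sequential deflation of X
# (classical PLS1 / univariate NIPALS). Each weight vector is the
# normalized covariance between the deflated predictor block and the
# outcome, so component 1 is proportional to cov(X, y) by construction;
# scores are mutually orthogonal; at full rank the fit coincides with
# ordinary least squares. Deterministic: no random initialization, and
# component signs are fixed by a stated convention (sum of predictor
# loadings <= 0, ties broken by a non-positive first loading) so the
# all-regions damage pattern reproducibly appears with negative FA
# loadings.

# bare-bones PLS1 used by both the user-facing fit and tests; X, y are
# assumed centered/standardized by the caller
pls1_core <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp)   # x weights (unit norm)
  P <- matrix(0, p, ncomp)   # x loadings
  Tm <- matrix(0, n, ncomp)  # x scores
  q <- numeric(ncomp)        # y loadings
  Xk <- X
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xk, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop_invariant("outcome covariance vanished at component ", k,
                     "; X is rank deficient for the requested n_components")
    w <- w / nw
    t_k <- Xk %*% w
    tt <- sum(t_k^2)
    if (tt < 1e-12)
      stop_invariant("degenerate score at component ", k)
    p_k <- crossprod(Xk, t_k) / tt
    q[k] <- sum(y * t_k) / tt
    Xk <- Xk - t_k %*% t(p_k)
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- t_k
  }
  list(W = W, P = P, T = Tm, q = q)
}

# regression coefficients for the first k components: B = W (P'W)^-1 q
pls1_coefficients <- function(core, k) {
  Wk <- core$W[, seq_len(k), drop = FALSE]
  Pk <- core$P[, seq_len(k), drop = FALSE]
  drop(Wk %*% solve(crossprod(Pk, Wk), core$q[seq_len(k)]))
}

check_standardized <- function(x, what, tol_mean = 1e-6, tol_sd = 1e-4) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  if (any(abs(mu) > tol_mean) || any(abs(s - 1) > tol_sd))
    stop_invariant(what, " must be standardized (mean 0, SD 1 per column); ",
                   "use zscore_columns() first")
}

#' Fit a single-outcome partial least squares (PLS1) model
#'
#' @param X Standardized predictor matrix (subjects by variables; for this
#'   pipeline, the five regional metrics, or ten for combined metrics).
#' @param y Standardized outcome vector (z-scored PTA days).
#' @param n_components Number of components, at most `min(rank(X), ncol(X))`.
#' @param center,scale Optional standardization constants of `X` recorded
#'   in the fit for reuse on held-out rows.
#' @param check Verify that `X` and `y` are standardized (default `TRUE`).
#' @return Object of class `pls1_fit` with `x_weights`, `x_loadings`
#'   (predictors by components), `y_loadings`, `x_scores` (subjects by
#'   components), `coefficients` (predictors by components; column k gives
#'   the regression coefficients using components 1..k), `pct_var_x` and
#'   `pct_var_y` (cumulative percent of predictor / outcome variance), and
#'   the normalization constants.
#' @export
#' @examples
#' set.seed(1)
#' X <- zscore_columns(matrix(rnorm(14 * 5), 14, 5))$x
#' y <- drop(zscore_columns(cbind(rnorm(14)))$x)
#' fit <- fit_pls1(X, y, n_components = 3)
#' round(fit$pct_var_x, 1)
fit_pls1 <- function(X, y, n_components = 3, center = NULL, scale = NULL,
                     check = TRUE) {
  X <- as.matrix(X)
  y <- drop(y)
  if (nrow(X) != length(y))
    stop_invariant("X and y must have one row/entry per subject")
  if (check) {
    check_standardized(X, "X")
    check_standardized(cbind(y), "y")
  }
  rk <- qr(X)$rank
  if (n_components > min(rk, ncol(X)))
    stop_invariant("n_components (", n_components,
                   ") exceeds the rank of X (", rk, ")")
  if (nrow(X) < n_components + 2)
    stop_invariant("need at least n_components + 2 subjects")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))

  core <- pls1_core(X, y, n_components)

  # sign convention: per component, sum of predictor loadings <= 0; exact
  # ties broken by making the first predictor's loading <= 0
  for (k in seq_len(n_components)) {
    s <- sum(core$P[, k])
    flip <- if (abs(s) > 1e-12) s > 0 else core$P[1L, k] > 0
    if (flip) {
      core$W[, k] <- -core$W[, k]; core$P[, k] <- -core$P[, k]
      core$T[, k] <- -core$T[, k]; core$q[k] <- -core$q[k]
    }
  }

  ssx <- sum(X^2); ssy <- sum(y^2)
  tt <- colSums(core$T^2)
  pct_var_x <- cumsum(colSums(core$P^2) * tt) / ssx * 100
  pct_var_y <- cumsum(core$q^2 * tt) / ssy * 100
  coefs <- vapply(seq_len(n_components), function(k) pls1_coefficients(core, k),
                  numeric(ncol(X)))
  coefs <- matrix(coefs, ncol = n_components,
                  dimnames = list(colnames(X), paste0("comp", seq_len(n_components))))

  structure(list(
    n_components = n_components,
    x_weights = structure(core$W, dimnames = dimnames(coefs)),
    x_loadings = structure(core$P, dimnames = dimnames(coefs)),
    y_loadings = core$q,
    x_scores = structure(core$T, dimnames = list(rownames(X),
                                                 colnames(coefs))),
    coefficients = coefs,
    pct_var_x = pct_var_x,
    pct_var_y = pct_var_y,
    center = center, scale = scale,
    predictors = colnames(X)),
    class = "pls1_fit")
}

#' Predict the standardized outcome from a PLS1 fit
#'
#' `newdata` must already be standardized with the fit's stored constants
#' (in leave-one-out use, the training fold's constants). Predictions are
#' on the standardized outcome scale, so a row at the training means
#' predicts 0.
#'
#' @param object A `pls1_fit`.
#' @param newdata Standardized matrix with the fit's predictor columns.
#' @param n_components Components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector of standardized predictions.
#' @export
predict.pls1_fit <- function(object, newdata, n_components = object$n_components,
                             ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$predictors))
    stop_invariant("newdata must have the fit's ", length(object$predictors),
                   " predictor columns")
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$predictors))
    stop_invariant("newdata columns do not match the training predictors (",
                   paste(object$predictors, collapse = ", "), ")")
  if (n_components > object$n_components)
    stop_invariant("fit has only ", object$n_components, " components")
  drop(newdata %*% object$coefficients[, n_components])
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat("PLS1 fit:", length(x$predictors), "predictors,",
      x$n_components, "components\n")
  cat("Cumulative % predictor variance:",
      paste(sprintf("%.1f", x$pct_var_x), collapse = ", "), "\n")
  cat("Cumulative % outcome variance:  ",
      paste(sprintf("%.1f", x$pct_var_y), collapse = ", "), "\n")
  invisible(x)
}

#' Smallest component count covering a variance threshold on all variables
#'
#' Returns the minimum k such that the k-th cumulative percent-variance
#' entry strictly exceeds `threshold` for every analyzed variable (the
#' "more than 80 percent on all four variables" rule).
#'
#' @param pct_var_tables Named list of nondecreasing cumulative
#'   percent-variance vectors, one per analyzed variable.
#' @param threshold Percent threshold (default 80), strict exceedance.
#' @return Integer component count.
#' @export
#' @examples
#' select_n_components(list(FA = c(50, 75, 86), MD = c(60, 80.5, 92),
#'                          MBv = c(70, 85, 96), MBc = c(66, 81, 96)))
select_n_components <- function(pct_var_tables, threshold = 80) {
  if (!length(pct_var_tables)) stop_invariant("no variance tables supplied")
  if (is.numeric(pct_var_tables)) pct_var_tables <- list(pct_var_tables)
  kmax <- min(lengths(pct_var_tables))
  for (k in seq_len(kmax)) {
    ok <- vapply(pct_var_tables, function(v) v[k] > threshold, logical(1))
    if (all(ok)) return(k)
  }
  short <- names(pct_var_tables)[
    !vapply(pct_var_tables, function(v) v[kmax] > threshold, logical(1))]
  if (!length(short)) short <- "unnamed"
  stop_invariant("variance threshold ", threshold,
                 "% never strictly exceeded for: ",
                 paste(short, collapse = ", "))
}
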