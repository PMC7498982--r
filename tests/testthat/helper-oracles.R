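# Independent oracles used across the suite. These deliberately share no
# code with the implementation: the PLS oracle goes through the Krylov-space
# characterization of PLS1 instead of deflation, erosion and nearest-label
# oracles are direct per-voxel scans, and Spearman is assembled from
# explicit mid-ranks and covariance sums.

# PLS1 fitted values via the Krylov-subspace equivalence: with s = X'y, the
# k-component PLS1 coefficient vector lies in span{s, (X'X)s, ...,
# (X'X)^(k-1) s} and solves the least-squares problem restricted to it.
krylov_pls1_beta <- function(X, y, k) {
  s <- crossprod(X, y)
  G <- crossprod(X)
  K <- matrix(0, ncol(X), k)
  v <- s
  for (j in seq_len(k)) {
    K[, j] <- v
    v <- G %*% v
  }
  a <- qr.solve(crossprod(K, G %*% K), crossprod(K, s))
  drop(K %*% a)
}

ols_fitted <- function(X, y) {
  drop(X %*% solve(crossprod(X), crossprod(X, y)))
}

# mid-rank Spearman from first principles
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent leave-one-out loop: per fold, standardize without the held-out
# row and predict it through the Krylov oracle
oracle_loocv <- function(X, y, k) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr); sdx <- apply(Xtr, 2, sd)
    muy <- mean(y[-i]); sdy <- sd(y[-i])
    Xs <- sweep(sweep(Xtr, 2, mu), 2, sdx, `/`)
    ys <- (y[-i] - muy) / sdy
    beta <- krylov_pls1_beta(Xs, ys, k)
    pred[i] <- sum((X[i, ] - mu) / sdx * beta)
  }
  pred
}

# brute-force 26-neighbourhood erosion by explicit neighbourhood scan
oracle_erode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
    if (all(mask[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1)]))
      out[x, y, z] <- TRUE
  }
  out
}

# brute-force nearest labeled voxel in physical coordinates, lowest label
# id on ties
oracle_nearest <- function(wm_mask, labels, voxel_size) {
  d <- dim(labels)
  lab_idx <- which(labels > 0, arr.ind = TRUE)
  out <- labels
  for (i in which(wm_mask)) {
    v <- arrayInd(i, d)
    dist2 <- colSums((t(sweep(lab_idx, 2, v)) * voxel_size)^2)
    best <- min(dist2)
    cand <- labels[lab_idx[dist2 <= best + 1e-12, , drop = FALSE]]
    out[i] <- min(cand)
  }
  out
}

# small standardized random PLS instance
random_standardized <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), `/`)
  y <- rnorm(n)
  y <- (y - mean(y)) / sd(y)
  list(X = X, y = y)
}

# single-metric FA cohort configs used by the inference suites
fa_only_specs <- function(effect_global = NULL, effect_deep = NULL) {
  sp <- ptapls:::default_metric_specs()["FA"]
  if (!is.null(effect_global)) sp$FA$effect_global <- effect_global
  if (!is.null(effect_deep)) sp$FA$effect_deep <- effect_deep
  sp
}

null_cohort <- function(seed) {
  generate_cohort(cohort_config(metrics = fa_only_specs(0, 0),
                                pta_coefs = c(190, 0, 0), seed = seed))
}
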