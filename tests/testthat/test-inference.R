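test_that("Spearman correlation handles monotone, reversed and tied data", {
  x <- c(3, 8, 1, 9, 2, 5, 7)
  expect_equal(spearman_corr(x, x^3, tail = "positive")$rho, 1)
  expect_equal(spearman_corr(x, -x, tail = "negative")$rho, -1)

  set.seed(4)
  for (rep in 1:20) {
    a <- sample(1:5, 12, replace = TRUE)  # heavy ties
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(spearman_corr(a, b, tail = "two")$rho, brute_spearman(a, b),
                 tolerance = 1e-12)
  }
})

test_that("one-tailed p-values are directed and complementary", {
  set.seed(10)
  x <- rnorm(12); y <- x + rnorm(12)
  pos <- spearman_corr(x, y, tail = "positive")
  neg <- spearman_corr(x, y, tail = "negative")
  two <- spearman_corr(x, y, tail = "two")
  expect_equal(pos$p + neg$p, 1, tolerance = 1e-12)
  expect_equal(two$p, 2 * min(pos$p, neg$p), tolerance = 1e-12)
  expect_lt(pos$p, neg$p)  # positive association

  expect_error(spearman_corr(rep(1, 6), rnorm(6)), "constant")
  expect_error(spearman_corr(1:3, 1:3), "at least 4")
  expect_error(spearman_corr(c(1, NA, 3, 4), 1:4), "non-finite")
})

test_that("component association flags exactly the sub-alpha components", {
  set.seed(11)
  inst <- random_standardized(14, 5, 70)
  fit <- fit_pls1(inst$X, inst$y, n_components = 3)
  assoc <- correlate_components(fit, inst$y, alpha_corrected = 0.05 / 3)
  expect_identical(assoc$significant, assoc$p < 0.05 / 3)
  expect_true(all(assoc$rho >= -1 & assoc$rho <= 1))
  expect_true(all(assoc$p > 0 & assoc$p <= 1))

  # scores equal to the outcome ranks: perfect association, flagged
  fit2 <- fit
  fit2$x_scores[, 1] <- rank(inst$y)
  a2 <- correlate_components(fit2, inst$y)
  expect_equal(a2$rho[1], 1)
  expect_true(a2$significant[1])
})

test_that("under the null the component flag rate is close to the corrected alpha", {
  set.seed(12)
  alpha <- 0.05 / 3
  scores <- matrix(rnorm(14 * 3), 14, 3)
  hits <- replicate(2000, {
    y <- rnorm(14)
    p <- vapply(1:3, function(k) spearman_corr(scores[, k], y,
                                               tail = "positive")$p,
                numeric(1))
    p < alpha
  })
  rate <- mean(hits)
  band <- qbinom(c(0.005, 0.995), 6000, alpha) / 6000
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("a perfect single predictor yields perfectly ranked held-out predictions", {
  set.seed(13)
  y <- rnorm(12) * 50 + 150
  pred <- loocv_predict(cbind(x = y), y, n_components = 1)
  expect_equal(spearman_corr(pred, y, tail = "positive")$rho, 1)
})

test_that("both LOOCV engines agree with each other and with the independent fold loop", {
  set.seed(14)
  for (rep in 1:5) {
    X <- matrix(rnorm(8 * 3), 8, 3)
    y <- rnorm(8)
    p_cpp <- loocv_predict(X, y, n_components = 2, engine = "cpp")
    p_r <- loocv_predict(X, y, n_components = 2, engine = "r")
    expect_equal(p_cpp, as.numeric(p_r), tolerance = 1e-10)
    expect_equal(p_cpp, oracle_loocv(X, y, 2), tolerance = 1e-8)
  }
})

test_that("the held-out subject's outcome never influences its own prediction", {
  set.seed(15)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rnorm(10) * 30 + 100
  pred <- loocv_predict(X, y, n_components = 3)
  for (i in c(1, 4, 10)) {
    y2 <- y
    y2[i] <- y2[i] + 500
    pred2 <- loocv_predict(X, y2, n_components = 3)
    expect_equal(pred2[i], pred[i], tolerance = 1e-12)
  }
})

test_that("LOOCV rejects unusable folds with fold and column named", {
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("FA_FT", "FA_PO")))
  X[2:8, 2] <- 1  # constant once row 1 leaves
  expect_error(loocv_predict(X, rnorm(8), 2), "FA_PO")
  expect_error(loocv_predict(X[, 1, drop = FALSE], rep(3, 8), 1),
               "outcome")
  expect_error(loocv_predict(matrix(rnorm(10), 5, 2), rnorm(5), 3),
               "n_components \\+ 3")
})

test_that("the permutation test is seeded, bounded, and exact at the boundary", {
  set.seed(16)
  coh <- generate_cohort(cohort_config(seed = 55))
  pat <- coh$subjects$group == "patient"
  X <- coh$metrics$FA[pat, ]
  y <- coh$subjects$pta_days[pat]

  r1 <- permutation_test(X, y, n_components = 3, B = 200, seed = 9)
  r2 <- permutation_test(X, y, n_components = 3, B = 200, seed = 9)
  expect_identical(r1$null_rho, r2$null_rho)
  expect_identical(r1$p, r2$p)
  expect_equal(r1$p_strict, mean(r1$null_rho > r1$observed_rho))
  expect_equal(r1$p_add_one,
               (1 + sum(r1$null_rho >= r1$observed_rho)) / 201)
  expect_error(permutation_test(X, y, B = 50), "at least 100")

  # perfect predictor: observed rho = 1 beats every null draw
  yy <- sort(rnorm(12) * 40 + 150)
  r3 <- permutation_test(cbind(a = yy), yy, n_components = 1, B = 100,
                         seed = 2)
  expect_equal(r3$observed_rho, 1)
  expect_identical(r3$p_strict, 0)
  expect_equal(r3$p_add_one, (1 + sum(r3$null_rho >= 1)) / 101)
})

test_that("fold-loading summaries have the right shape and finite spread", {
  coh <- generate_cohort(cohort_config(seed = 77))
  pat <- coh$subjects$group == "patient"
  res <- permutation_test(coh$metrics$FA[pat, ], coh$subjects$pta_days[pat],
                          n_components = 3, B = 100, seed = 1)
  expect_identical(dim(res$loading_mean), c(5L, 3L))
  expect_identical(dim(res$loading_se), c(5L, 3L))
  expect_true(all(is.finite(res$loading_se)) && all(res$loading_se >= 0))
})
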