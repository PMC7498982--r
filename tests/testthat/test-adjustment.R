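make_hc <- function(n, f, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ages <- runif(n, 20, 70)
  x <- sapply(pta_regions(), function(r) f(ages))
  rownames(x) <- paste0("C", seq_len(n))
  list(x = x, ages = ages)
}

test_that("a noiseless linear age trend is recovered to machine precision", {
  hc <- make_hc(10, function(a) 0.5 - 0.001 * a, seed = 1)
  tr <- fit_age_trends(hc$x, hc$ages, metric_name = "FA")
  expect_equal(tr$slope, rep(-0.001, 5), tolerance = 1e-12)
  expect_equal(tr$intercept, rep(0.5, 5), tolerance = 1e-12)
  expect_equal(tr$reference_age, rep(mean(hc$ages), 5))

  flat <- make_hc(8, function(a) rep(0.4, length(a)), seed = 2)
  tr2 <- fit_age_trends(flat$x, flat$ages)
  expect_equal(tr2$slope, rep(0, 5), tolerance = 1e-12)
})

test_that("fitted trends equal the closed-form least-squares solution", {
  set.seed(33)
  ages <- runif(10, 20, 70)
  x <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, pta_regions()))
  tr <- fit_age_trends(x, ages, metric_name = "m")
  for (i in 1:5) {
    v <- x[, i]
    slope <- (sum(ages * v) - length(v) * mean(ages) * mean(v)) /
      (sum(ages^2) - length(v) * mean(ages)^2)
    expect_equal(tr$slope[i], slope, tolerance = 1e-10)
    expect_equal(tr$intercept[i], mean(v) - slope * mean(ages),
                 tolerance = 1e-10)
  }
})

test_that("degenerate control data is refused with the offending pair named", {
  x <- matrix(1:6 / 10, 3, 2, dimnames = list(NULL, c("FT", "PO")))
  expect_error(fit_age_trends(x, c(40, 40, 40)), "degenerate control ages")
  expect_error(fit_age_trends(x[1:2, ], c(30, 40)), ">= 3 controls")
})

test_that("slope-only adjustment is the identity at zero slope and at the reference age", {
  set.seed(7)
  x <- matrix(rnorm(40, 0.5, 0.05), 8, 5, dimnames = list(NULL, pta_regions()))
  tr <- data.frame(metric = "metric", region = pta_regions(), slope = 0,
                   intercept = 0.5, reference_age = 41, n_controls = 21)
  expect_equal(apply_age_adjustment(x, runif(8, 20, 70), tr), x)

  tr$slope <- -0.002
  at_ref <- apply_age_adjustment(x, rep(41, 8), tr)
  expect_equal(at_ref, x)
})

test_that("patients generated on a known trend flatten to the reference-age value", {
  sp <- ptapls:::default_metric_specs()["FA"]
  sp$FA$effect_global <- 0; sp$FA$effect_deep <- 0; sp$FA$noise_sd <- 0
  coh <- generate_cohort(cohort_config(metrics = sp, seed = 12))
  pat <- coh$subjects$group == "patient"
  tr <- fit_age_trends(coh$metrics$FA[!pat, ], coh$subjects$age[!pat],
                       metric_name = "FA")
  adj <- apply_age_adjustment(coh$metrics$FA[pat, ], coh$subjects$age[pat],
                              tr, metric_name = "FA")
  for (r in pta_regions()) {
    expect_lt(diff(range(adj[, r])), 1e-10)  # constant across ages
    expect_equal(unname(adj[1, r]),
                 sp$FA$baselines[[r]] + sp$FA$age_slopes[[r]] * tr$reference_age[1],
                 tolerance = 1e-10)
  }
  # residual method differs only by a per-column constant
  adj2 <- apply_age_adjustment(coh$metrics$FA[pat, ], coh$subjects$age[pat],
                               tr, method = "residual", metric_name = "FA")
  expect_lt(max(abs(sweep(adj - adj2, 2, colMeans(adj - adj2)))), 1e-10)

  expect_error(apply_age_adjustment(coh$metrics$FA[pat, ],
                                    coh$subjects$age[pat],
                                    tr[tr$region != "CC", ],
                                    metric_name = "FA"),
               "CC")
})

test_that("re-fitting trends on adjusted control data yields zero slopes", {
  coh <- generate_cohort(cohort_config(seed = 23))
  ctrl <- coh$subjects$group == "control"
  tr <- fit_age_trends(coh$metrics$FA[ctrl, ], coh$subjects$age[ctrl],
                       metric_name = "FA")
  adj <- apply_age_adjustment(coh$metrics$FA[ctrl, ], coh$subjects$age[ctrl],
                              tr, metric_name = "FA")
  tr2 <- fit_age_trends(adj, coh$subjects$age[ctrl], metric_name = "FA")
  expect_equal(tr2$slope, rep(0, 5), tolerance = 1e-10)
})

test_that("z-scoring matches hand arithmetic, is idempotent, and names bad columns", {
  z <- zscore_columns(cbind(a = c(1, 2, 3)))
  expect_equal(as.vector(z$x), c(-1, 0, 1))
  expect_equal(z$center[["a"]], 2)
  expect_equal(z$scale[["a"]], 1)

  set.seed(9)
  x <- matrix(rnorm(60, 5, 3), 12, 5)
  z1 <- zscore_columns(x)
  for (j in 1:5) {
    expect_lt(abs(sum(z1$x[, j]) / 12), 1e-12)
    expect_equal(sqrt(sum((z1$x[, j] - mean(z1$x[, j]))^2) / 11), 1,
                 tolerance = 1e-12)
  }
  z2 <- zscore_columns(z1$x)
  expect_equal(z2$x, z1$x, tolerance = 1e-12)

  expect_error(zscore_columns(cbind(ok = rnorm(5), flat = rep(2, 5))), "flat")
})

test_that("adjustment preserves subject ranking at any fixed age", {
  set.seed(41)
  x <- matrix(rnorm(40, 0.45, 0.05), 8, 5, dimnames = list(NULL, pta_regions()))
  tr <- data.frame(metric = "metric", region = pta_regions(), slope = -0.002,
                   intercept = 0.5, reference_age = 45, n_controls = 10)
  adj <- apply_age_adjustment(x, rep(60, 8), tr)
  for (r in pta_regions())
    expect_identical(order(adj[, r]), order(x[, r]))
})
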