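test_that("AIC/AICc follow the printed formulas", {
  ic <- aic_aicc(-100, 0, 50)
  expect_equal(ic$aic, 200)
  expect_equal(ic$aicc, 200)
  ic2 <- aic_aicc(-100, 3, 10)
  expect_equal(ic2$aic, 206)
  expect_equal(ic2$aicc, 210)
  expect_error(aic_aicc(-100, 3, 4), "AICc")
  expect_true(aic_meaningful(3))
  expect_false(aic_meaningful(2.9))
})

test_that("likelihood ratio test uses the chi-square upper tail", {
  eq <- likelihood_ratio_test(-100, -100, 1)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  lrt <- likelihood_ratio_test(-105, -100, 1)
  expect_equal(lrt$statistic, 10)
  expect_equal(lrt$p.value, pchisq(10, 1, lower.tail = FALSE))
  expect_lt(abs(lrt$p.value - 0.00157), 2e-5)
  expect_error(likelihood_ratio_test(-100, -105, 1), "nested")
  expect_error(likelihood_ratio_test(-105, -100, 0), "df")
})

test_that("concordance follows the censoring-aware pair rules", {
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  # A: event t=1 risk 3; B: censored t=2 risk 1; C: event t=3 risk 2
  # evaluable pairs {A,B}, {A,C}; both concordant
  expect_equal(concordance_index(c(3, 1, 2), c(1, 2, 3), c(1, 0, 1)), 1)
  expect_error(concordance_index(c(1, 2), c(1, 2), c(0, 0)), "evaluable")
})

test_that("concordance equals the brute-force pair enumeration", {
  for (s in 1:25) {
    set.seed(20 + s)
    n <- sample(5:40, 1)
    oc <- sim_outcomes(n, cens_rate = runif(1, 0.3, 2))
    risk <- sample(round(rnorm(n), 2)) # induces occasional risk ties
    skip <- tryCatch({
      a <- concordance_index(risk, oc$time, oc$event)
      FALSE
    }, error = function(e) TRUE)
    if (skip) next
    expect_equal(a, oracle_cindex(risk, oc$time, oc$event),
                 tolerance = 1e-12)
  }
})

test_that("random risk scores score at chance concordance", {
  cs <- vapply(1:50, function(s) {
    set.seed(600 + s)
    oc <- sim_outcomes(200)
    concordance_index(rnorm(200), oc$time, oc$event)
  }, numeric(1))
  expect_lt(abs(mean(cs) - 0.5), 0.05)
})

test_that("Brier score identities hold and IPCW matches a hand computation", {
  set.seed(26)
  oc <- sim_outcomes(50, cens_rate = 1e-9) # effectively no censoring
  oc$event <- rep(1L, 50)
  expect_equal(brier_ipcw(rep(0.5, 50), oc$time, oc$event, horizon = 1),
               0.25)
  truth <- as.numeric(oc$time <= 1)
  expect_equal(brier_ipcw(truth, oc$time, oc$event, horizon = 1), 0)

  # 4 subjects, one censored before the horizon:
  # G has a censoring jump at t=4 (risk 3) so G = 2/3 beyond it;
  # weights: event@2 -> 1, censored@4 -> 0, at-risk@6,8 -> 1.5
  p <- c(0.8, 0.5, 0.3, 0.1)
  b <- brier_ipcw(p, c(2, 4, 6, 8), c(1, 0, 1, 0), horizon = 5)
  expect_equal(b, (1 * 0.2^2 + 1.5 * 0.3^2 + 1.5 * 0.1^2) / 4)
})

test_that("AUC at a horizon reduces to the rank-sum statistic", {
  tm <- c(1, 2, 3, 10, 11, 12)
  ev <- rep(1L, 6)
  expect_equal(auc_at_horizon(c(.9, .8, .7, .2, .3, .1), tm, ev, 5), 1)
  expect_equal(auc_at_horizon(c(.1, .2, .3, .9, .8, .7), tm, ev, 5), 0)
  set.seed(27)
  p <- runif(6)
  cases <- which(tm <= 5)
  controls <- which(tm > 5)
  mw <- mean(outer(p[cases], p[controls],
                   function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc_at_horizon(p, tm, ev, 5), mw)
  expect_error(auc_at_horizon(p, tm, rep(0L, 6), 0.5), "case")
})

test_that("Nam-D'Agostino calibration detects exact agreement as zero", {
  # two bins of 10; predictions equal the realised event proportions
  tm <- c(rep(1, 2), rep(10, 8), rep(1, 6), rep(10, 4))
  ev <- rep(1L, 20)
  p <- c(rep(0.2, 10), rep(0.6, 10))
  nd <- nam_dagostino(p, tm, ev, horizon = 5, n_bins = 2)
  expect_equal(nd$statistic, 0, tolerance = 1e-12)
  expect_identical(nd$df, 0L)

  # hand-computed two-bin statistic with miscalibrated predictions
  p2 <- c(rep(0.4, 10), rep(0.5, 10))
  nd2 <- nam_dagostino(p2, tm, ev, horizon = 5, n_bins = 2)
  hand <- 10 * (0.2 - 0.4)^2 / (0.4 * 0.6) + 10 * (0.6 - 0.5)^2 / (0.5 * 0.5)
  expect_equal(nd2$statistic, hand, tolerance = 1e-12)
  expect_gte(nd2$statistic, 0)
  # deciles give the conventional 8 degrees of freedom
  set.seed(28)
  oc <- sim_outcomes(200, cens_rate = 0.5)
  nd10 <- nam_dagostino(runif(200, 0.05, 0.95), oc$time, oc$event, 1)
  expect_identical(nd10$df, 8L)
})

test_that("adjusted Rand index matches pair counting and mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  for (s in 1:20) {
    set.seed(40 + s)
    n <- sample(6:30, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    # invariant to relabeling within a partition
    expect_equal(adjusted_rand_index(4 - a, b), adjusted_rand_index(a, b))
  }
  expect_error(adjusted_rand_index(integer(), integer()), "non-empty")
})
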