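test_that("min-max standardization maps training ranges onto [0, 1]", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  std <- minmax_standardize(x)
  expect_equal(unname(std$values[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(std$values[, "b"]), c(0, 0, 0)) # constant column rule
  # validation transform uses training ranges and clips
  expect_equal(unname(apply_standardization(std, cbind(a = 8, b = 5))[1, 1]),
               1.0) # (8-2)/4 = 1.5, clipped
  lo <- cbind(a = 2, b = 5)
  hi <- cbind(a = 6, b = 5)
  expect_equal(unname(apply_standardization(std, lo)[1, ]), c(0, 0))
  expect_equal(unname(apply_standardization(std, hi)[1, ]), c(1, 0))
  mid <- cbind(a = 4, b = 5)
  expect_equal(unname(apply_standardization(std, mid)[1, "a"]), 0.5)
  # idempotence on the training data itself
  expect_equal(apply_standardization(std, x), std$values,
               ignore_attr = TRUE)
  expect_error(apply_standardization(std, cbind(z = 1)), "mismatch")
})

test_that("PMM imputes from observed support only and is deterministic", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(pmm_impute(x, seed = 1)$completed, x) # nothing to impute

  xm <- x
  xm[c(2, 5), "b"] <- NA
  xm[9, "c"] <- NA
  f1 <- pmm_impute(xm, seed = 4)
  f2 <- pmm_impute(xm, seed = 4)
  expect_identical(f1$completed, f2$completed)
  expect_true(all(f1$completed[c(2, 5), "b"] %in% x[-c(2, 5), "b"]))
  expect_true(all(f1$completed[9, "c"] %in% x[-9, "c"]))
  expect_error(pmm_impute(cbind(a = c(NA, NA), b = c(1, 2))), "entirely")
})

test_that("one PMM step with a perfect predictor picks the nearest donor", {
  # x2 = 2 * x1 exactly on observed rows; the row-3 prediction (6.4) is
  # nearest to donor prediction 8, so with k = 1 the imputed value is 8
  x <- cbind(x1 = c(1, 2, 3.2, 4, 5), x2 = c(2, 4, NA, 8, 10))
  fit <- pmm_impute(x, k_donors = 1, n_cycles = 1, seed = 1)
  expect_equal(unname(fit$completed[3, "x2"]), 8)
})

test_that("validation rows impute individually, independently and in any order", {
  set.seed(2)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  xm <- x
  xm[sample(80, 12)] <- NA
  fit <- pmm_impute(xm, seed = 7)

  full_row <- x[1, ]
  expect_equal(impute_validation_row(fit, full_row, seed = 3), full_row)

  r1 <- c(f1 = 0.3, f2 = NA, f3 = -0.2, f4 = NA)
  r2 <- c(f1 = NA, f2 = 1.1, f3 = 0.4, f4 = 0.0)
  a1 <- impute_validation_row(fit, r1, seed = 5)
  expect_identical(impute_validation_row(fit, r1, seed = 5), a1)
  # imputing r2 first must not change r1's result
  b2 <- impute_validation_row(fit, r2, seed = 6)
  a1_after <- impute_validation_row(fit, r1, seed = 5)
  expect_identical(a1_after, a1)
  expect_true(all(!is.na(a1)) && all(!is.na(b2)))
  expect_error(impute_validation_row(fit, c(f1 = NA, f2 = NA, f3 = NA,
                                            f4 = NA)), "all features")
})

test_that("variance and correlation filters drop the right columns", {
  set.seed(3)
  n <- 50
  anchor <- rnorm(n)
  near <- anchor + rnorm(n, sd = 0.30)   # |r| ~ 0.95 with the anchor
  far <- 0.5 * scale(anchor)[, 1] + sqrt(1 - 0.25) * rnorm(n) # r ~ 0.5
  x <- cbind(anchor = anchor, dup1 = anchor * 2 + 1, near = near,
             far = far, flat = rep(3, n))
  stopifnot(abs(cor(near, anchor)) > 0.80, abs(cor(far, anchor)) < 0.8)
  res <- variance_correlation_filter(x, anchors = "anchor")
  expect_false("flat" %in% res$keep)       # zero variance
  expect_false("dup1" %in% res$keep)       # r = 1 duplicate, earlier kept
  expect_true("anchor" %in% res$keep)
  expect_false("near" %in% res$keep)       # r > 0.80 with the anchor
  expect_true("far" %in% res$keep)
  expect_setequal(res$dropped$feature, c("flat", "dup1", "near"))
  expect_error(variance_correlation_filter(x, anchors = "missing"),
               "anchor")
})

test_that("exact duplicates leave exactly one survivor, input order kept", {
  set.seed(4)
  a <- rnorm(30)
  x <- cbind(p = a, q = a, r = rnorm(30))
  res <- variance_correlation_filter(x)
  expect_identical(res$keep, c("p", "r"))
})

test_that("RReliefF weights are bounded and rank a perfect signal first", {
  set.seed(5)
  n <- 300
  signal <- runif(n)
  x <- cbind(signal = signal,
             matrix(runif(n * 10), n, 10,
                    dimnames = list(NULL, paste0("noise", 1:10))),
             flat = rep(0.5, n))
  w <- rrelieff(x, y = signal, n_iterations = 300, seed = 6)
  expect_true(all(abs(w) <= 1))
  expect_equal(unname(w["flat"]), 0) # constant feature never differs
  expect_identical(names(which.max(unclass(w))), "signal")
  expect_identical(select_top_m(w, 1), "signal")
  expect_error(rrelieff(x, signal, k_neighbors = n), "k_neighbors")
})

test_that("RReliefF separates signal from noise in nearly all replicates", {
  ok <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 300
    sig <- runif(n)
    y <- sig + rnorm(n, sd = 0.1)
    x <- cbind(signal = sig,
               matrix(runif(n * 5), n, 5,
                      dimnames = list(NULL, paste0("noise", 1:5))))
    w <- rrelieff(x, y, n_iterations = 300, seed = 300 + s)
    names(which.max(unclass(w))) == "signal"
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
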