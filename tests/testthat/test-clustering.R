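test_that("k-medians handles the degenerate and hand-checked cases", {
  set.seed(15)
  x <- matrix(runif(12), 6, 2)
  kn <- kmedians(x, k = 6, seed = 1)
  expect_equal(kn$cost, 0)
  expect_length(unique(kn$labels), 6)

  k1 <- kmedians(x, k = 1, seed = 1)
  expect_equal(unname(k1$medians[1, ]), apply(x, 2, median))

  pts <- matrix(c(0, 0, 0, 1, 10, 10, 10, 11), ncol = 2, byrow = TRUE)
  k2 <- kmedians(pts, k = 2, seed = 3, nstart = 5)
  expect_equal(k2$labels[1], k2$labels[2])
  expect_equal(k2$labels[3], k2$labels[4])
  expect_false(k2$labels[1] == k2$labels[3])
  meds <- k2$medians[order(k2$medians[, 1]), ]
  expect_equal(unname(meds), matrix(c(0, 0.5, 10, 10.5), 2, byrow = TRUE))

  expect_error(kmedians(pts, k = 5), "exceeds")
  expect_error(kmedians(pts[0, , drop = FALSE], k = 1), "empty")
})

test_that("k-medians cost is non-increasing across iterations", {
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(rnorm(60 * 4), 60, 4)
    fit <- kmedians(x, 3, seed = s)
    expect_true(all(diff(fit$cost_trace) <= 1e-10))
  }
})

test_that("consensus matrix is a valid co-clustering summary", {
  set.seed(16)
  blob1 <- matrix(rnorm(20, 0, 0.1), 10, 2)
  blob2 <- matrix(rnorm(20, 10, 0.1), 10, 2)
  x <- rbind(blob1, blob2)
  cc <- consensus_cluster(x, k = 2, n_runs = 60, seed = 4)
  expect_equal(diag(cc$consensus), rep(1, 20))
  expect_true(isSymmetric(cc$consensus))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))
  within <- c(cc$consensus[1:10, 1:10], cc$consensus[11:20, 11:20])
  cross <- cc$consensus[1:10, 11:20]
  expect_equal(unique(as.vector(within)), 1)
  expect_equal(unique(as.vector(cross)), 0)
  # extraction equals the single exhaustive k-medians solution
  ref <- kmedians(x, 2, seed = 5, nstart = 10)
  expect_equal(adjusted_rand_index(cc$model$labels, ref$labels), 1)
  # permuting the subjects permutes the consensus matrix identically
  perm <- sample(20)
  cc_p <- consensus_cluster(x[perm, ], k = 2, n_runs = 60, seed = 9)
  expect_equal(cc_p$consensus, cc$consensus[perm, perm])
})

test_that("a single full-sample run reproduces its own clusters", {
  set.seed(17)
  x <- matrix(runif(30), 15, 2)
  cc <- consensus_cluster(x, k = 2, n_runs = 1, subsample_fraction = 1,
                          seed = 21)
  expect_true(all(cc$consensus %in% c(0, 1)))
  run <- single_run_labels(21, x)
  expect_equal(adjusted_rand_index(cc$model$labels, run), 1)
})

test_that("new points go to the nearest median with a stable tie rule", {
  model <- structure(list(k = 2,
                          medians = matrix(c(0, 0.5, 10, 10.5), 2,
                                           byrow = TRUE),
                          labels = c(1L, 2L)), class = "cluster_model")
  expect_equal(assign_to_clusters(model, model$medians), c(1L, 2L))
  expect_equal(assign_to_clusters(model, matrix(c(9, 9), 1)), 2L)
  expect_equal(assign_to_clusters(model, matrix(c(5, 5.5), 1)), 1L) # tie
  expect_error(assign_to_clusters(model, matrix(1, 1, 3)), "dimension")
})

test_that("fold labels align to the reference by majority agreement", {
  a <- c(1L, 1L, 2L, 2L, 1L)
  expect_identical(match_fold_labels(a, a), a)
  expect_identical(match_fold_labels(a, 3L - a), 3L - a)
  ref60 <- c(1L, 1L, 2L, 1L, 2L) # 60% agreement -> unchanged
  expect_identical(match_fold_labels(a, ref60), a)
  ref40 <- c(2L, 2L, 1L, 2L, 1L) # 40% agreement -> inverted
  expect_identical(match_fold_labels(a, ref40), 3L - a)
  tie <- c(1L, 2L, 1L, 2L)
  expect_identical(match_fold_labels(tie, c(1L, 1L, 2L, 2L)), tie)
  expect_error(match_fold_labels(c(1L, 3L), c(1L, 2L)), "two clusters")
})

test_that("scaled clustering recovers strong latent structure", {
  # hazard ratio 3 and separation 2; sized so the residual regression has
  # enough events to estimate the weights accurately
  hits <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_subjects = 1000, n_binary_features = 4,
                         n_continuous_features = 4, n_noise_features = 2,
                         latent_hazard_ratio = 3, group_separation = 2,
                         target_censoring_fraction = 0.3,
                         missing_rate = 0, seed = 400 + s)
    co <- generate_cohort(cfg)
    std <- minmax_standardize(co$features)
    res <- null_martingale_residuals(co$time, co$event)
    w <- fit_scaling_weights(std, res)
    sc <- apply_scaling(std, w)
    cc <- consensus_cluster(sc, k = 2, n_runs = 50, seed = 500 + s)
    ari <- adjusted_rand_index(cc$model$labels, co$latent_group)
    # training points reassigned to the medians reproduce the labels
    agree <- mean(assign_to_clusters(cc$model, sc) == cc$model$labels)
    (ari > 0.8) && (agree >= 0.95)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
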