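#' k-medians clustering with Manhattan distance
#'
#' Lloyd-style alternation: k-means++-style seeding (D(x)^2 sampling with
#' Manhattan D), assignment of each point to its nearest median (ties to the
#' lowest cluster index), and coordinate-wise median updates, until the
#' labels stabilise or `max_iter` is reached. The total Manhattan cost is
#' non-increasing across iterations. `nstart` independent restarts keep the
#' solution with the lowest total cost, as in [stats::kmeans()].
#'
#' @param x numeric matrix of points (rows).
#' @param k number of clusters (<= number of rows).
#' @param seed integer seed (drives seeding and restarts).
#' @param nstart number of random restarts (best cost kept).
#' @param max_iter maximum Lloyd iterations per restart.
#' @return object of class `kmedians_fit`: `labels` (1..k), `medians`
#'   (k x p), `cost`, `cost_trace`, `iterations`.
#' @export
kmedians <- function(x, k, seed = NULL, nstart = 1L, max_iter = 300L) {
  x <- as_feature_matrix(x)
  if (nrow(x) == 0L) stop("empty input", call. = FALSE)
  k <- assert_count(k, "k", min = 1L)
  if (k > nrow(x)) stop("k exceeds the number of points", call. = FALSE)
  nstart <- assert_count(nstart, "nstart", min = 1L)
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      res <- kmedians_once_cpp(x, k, as.integer(max_iter))
      if (is.null(best) || res$cost < best$cost) best <- res
    }
    colnames(best$medians) <- colnames(x)
    structure(list(labels = best$labels, medians = best$medians,
                   cost = best$cost, cost_trace = best$cost_trace,
                   iterations = best$iterations),
              class = "kmedians_fit")
  })
}

#' Consensus clustering over repeated subsampled k-medians runs
#'
#' For each of `n_runs` runs, a fraction of the subjects is subsampled and
#' k-medians is run with a fresh k-means++ seeding; the connectivity matrix
#' M counts how often a pair lands in the same cluster and the indicator
#' matrix I how often the pair was co-sampled. The consensus matrix is the
#' elementwise ratio M(i,j) = sum_h M^(h)(i,j) / sum_h I^(h)(i,j).
#' Average-linkage hierarchical clustering on the dissimilarity 1 - M,
#' cut at k clusters, extracts the final groups; medians are then recomputed
#' coordinate-wise from the extracted member sets.
#'
#' @param x numeric matrix of points in the (scaled) feature space.
#' @param k number of clusters (default 2).
#' @param n_runs number of k-medians runs (default 1000).
#' @param subsample_fraction fraction of subjects sampled per run
#'   (default 0.8).
#' @param seed integer seed.
#' @param max_iter per-run Lloyd iteration cap.
#' @return list with `model` (class `cluster_model`: `k`, `medians`,
#'   `labels`) and `consensus` (the N x N consensus matrix).
#' @export
consensus_cluster <- function(x, k = 2L, n_runs = 1000L,
                              subsample_fraction = 0.8, seed = NULL,
                              max_iter = 100L) {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  k <- assert_count(k, "k", min = 1L)
  if (n < k) stop("fewer points than clusters", call. = FALSE)
  n_runs <- assert_count(n_runs, "n_runs", min = 1L)
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1)
  m <- max(k, ceiling(subsample_fraction * n))
  M <- matrix(0, n, n)
  I <- matrix(0, n, n)
  with_seed(seed, {
    for (h in seq_len(n_runs)) {
      idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
      run <- kmedians_once_cpp(x[idx, , drop = FALSE], k,
                               as.integer(max_iter))
      consensus_accumulate_cpp(M, I, as.integer(idx - 1L),
                               as.integer(run$labels))
    }
  })
  if (any(I == 0))
    stop("some subject pair was never co-sampled; increase n_runs or ",
         "subsample_fraction", call. = FALSE)
  consensus <- M / I
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  labels <- stats::cutree(hc, k = k)
  medians <- t(vapply(seq_len(k), function(c)
    apply(x[labels == c, , drop = FALSE], 2L, stats::median),
    numeric(ncol(x))))
  colnames(medians) <- colnames(x)
  model <- structure(list(k = k, medians = medians,
                          labels = as.integer(labels)),
                     class = "cluster_model")
  list(model = model, consensus = consensus)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d, sizes %s\n", x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Assign new points to the nearest cluster median
#'
#' Points must live in the same scaled space as the model (standardized with
#' the training ranges, scaled with the training weights). Ties go to the
#' lowest cluster index.
#'
#' @param model a `cluster_model` (or a `kmedians_fit`).
#' @param new_points numeric matrix of points.
#' @return integer labels in 1..k.
#' @export
assign_to_clusters <- function(model, new_points) {
  medians <- model$medians
  new_points <- as_feature_matrix(new_points)
  if (ncol(new_points) != ncol(medians))
    stop("dimension mismatch between points and cluster medians",
         call. = FALSE)
  if (!is.null(colnames(medians)) &&
      all(colnames(medians) %in% colnames(new_points)))
    new_points <- new_points[, colnames(medians), drop = FALSE]
  d <- manhattan_to_rows(new_points, medians)
  apply(d, 1L, which.min)  # which.min takes the first (lowest index) on ties
}

#' Align a fold's binary cluster labels to a reference fold
#'
#' If the labels agree with the reference on more than half of the shared
#' subjects they are kept; if they agree on fewer than half they are
#' inverted (1 <-> 2); exactly half keeps them unchanged.
#'
#' @param labels integer labels in {1, 2} for this fold's subjects.
#' @param reference_labels labels from the reference fold.
#' @param shared_index optional index vectors: either a single vector valid
#'   for both, or a list with `labels` and `reference` positions of the
#'   shared subjects. Default compares the full vectors.
#' @return the (possibly inverted) labels.
#' @export
match_fold_labels <- function(labels, reference_labels,
                              shared_index = NULL) {
  lab_k <- sort(unique(c(labels, reference_labels)))
  if (!all(lab_k %in% 1:2))
    stop("label matching is defined for two clusters only (labels 1/2)",
         call. = FALSE)
  if (is.null(shared_index)) {
    a <- labels
    b <- reference_labels
  } else if (is.list(shared_index)) {
    a <- labels[shared_index$labels]
    b <- reference_labels[shared_index$reference]
  } else {
    a <- labels[shared_index]
    b <- reference_labels[shared_index]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  if (mean(a == b) < 0.5) labels <- 3L - labels
  labels
}

#' Write a consensus matrix as dense CSV (for heatmap inspection)
#' @param consensus N x N consensus matrix.
#' @param path output file.
#' @export
write_consensus_csv <- function(consensus, path) {
  utils::write.csv(consensus, path, row.names = FALSE)
  invisible(path)
}
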