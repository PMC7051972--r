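#' Min-max standardization with stored training ranges
#'
#' Affinely maps each training column so its minimum becomes 0 and maximum 1.
#' The per-column ranges are stored so that validation rows can later be
#' transformed with the *training* ranges ([apply_standardization()]), where
#' out-of-range values are clipped back into [0, 1] to keep Manhattan
#' distances bounded. Constant columns map to 0.
#'
#' @param x numeric matrix or data frame with no missing values.
#' @return object of class `standardized_matrix` with `values` (matrix in
#'   [0, 1]) and `ranges` (2 x p matrix of training min/max).
#' @export
minmax_standardize <- function(x) {
  x <- as_feature_matrix(x)
  if (anyNA(x))
    stop("missing values present; impute before standardizing", call. = FALSE)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  span <- hi - lo
  vals <- sweep(x, 2L, lo, "-")
  nz <- span > 0
  vals[, nz] <- sweep(vals[, nz, drop = FALSE], 2L, span[nz], "/")
  vals[, !nz] <- 0
  structure(list(values = vals,
                 ranges = rbind(min = lo, max = hi)),
            class = "standardized_matrix")
}

#' Apply stored training ranges to new rows
#'
#' @param std a `standardized_matrix` (the training fit).
#' @param new_rows numeric matrix/data frame with the same feature names.
#' @return matrix of transformed rows, clipped to [0, 1]. `NA` cells pass
#'   through unchanged (useful before imputation diagnostics).
#' @export
apply_standardization <- function(std, new_rows) {
  stopifnot(inherits(std, "standardized_matrix"))
  new_rows <- as_feature_matrix(new_rows)
  tr_names <- colnames(std$ranges)
  if (!identical(colnames(new_rows), tr_names)) {
    if (!all(tr_names %in% colnames(new_rows)))
      stop("feature mismatch between training ranges and new rows",
           call. = FALSE)
    new_rows <- new_rows[, tr_names, drop = FALSE]
  }
  lo <- std$ranges["min", ]
  span <- std$ranges["max", ] - lo
  vals <- sweep(new_rows, 2L, lo, "-")
  nz <- span > 0
  vals[, nz] <- sweep(vals[, nz, drop = FALSE], 2L, span[nz], "/")
  vals[, !nz] <- 0
  pmin(pmax(vals, 0), 1)
}

# least-squares fit of column j on all other columns over observed rows;
# aliased coefficients are treated as zero
pmm_fit_one <- function(x, j, obs) {
  design <- cbind(1, x[obs, -j, drop = FALSE])
  fit <- stats::lm.fit(design, x[obs, j])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  beta
}

pmm_predict <- function(beta, x, j) {
  drop(cbind(1, x[, -j, drop = FALSE]) %*% beta)
}

#' Predictive-mean-matching imputation by chained equations
#'
#' Chained linear-model PMM: missing cells are first filled with column
#' medians; then for a fixed number of cycles each incomplete feature is
#' regressed (ordinary least squares) on the other, current-iteration,
#' features over its observed rows; each missing cell receives the observed
#' value of one of the `k_donors` observed rows whose predicted values are
#' closest to the missing cell's prediction, the donor drawn uniformly.
#' Imputed values therefore always belong to the observed support of their
#' column.
#'
#' @param x numeric matrix/data frame, `NA` marks missing cells.
#' @param k_donors donor pool size (default 5).
#' @param n_cycles chained-equation cycles (default 5).
#' @param seed integer seed; results are deterministic given it.
#' @return object of class `pmm_fit`: `completed` matrix plus the fitted
#'   per-feature models needed to impute validation rows later.
#' @export
pmm_impute <- function(x, k_donors = 5L, n_cycles = 5L, seed = NULL) {
  x <- as_feature_matrix(x)
  k_donors <- assert_count(k_donors, "k_donors", min = 1L)
  miss <- is.na(x)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing))
    stop("feature(s) entirely missing: ",
         paste(colnames(x)[all_missing], collapse = ", "), call. = FALSE)
  incomplete <- which(colSums(miss) > 0L)
  completed <- x
  for (j in seq_len(ncol(x))) {
    if (any(miss[, j]))
      completed[miss[, j], j] <- stats::median(x[, j], na.rm = TRUE)
  }
  models <- list()
  if (length(incomplete)) {
    with_seed(seed, {
      for (cycle in seq_len(n_cycles)) {
        for (j in incomplete) {
          obs <- !miss[, j]
          beta <- pmm_fit_one(completed, j, obs)
          pred <- pmm_predict(beta, completed, j)
          donors_pred <- pred[obs]
          donors_val <- x[obs, j]
          for (i in which(miss[, j])) {
            d <- abs(donors_pred - pred[i])
            pool <- order(d)[seq_len(min(k_donors, length(d)))]
            completed[i, j] <- donors_val[pool[sample.int(length(pool), 1L)]]
          }
          models[[colnames(x)[j]]] <-
            list(beta = beta, donors_pred = donors_pred,
                 donors_val = donors_val, j = j)
        }
      }
    })
  }
  structure(list(completed = completed, models = models,
                 feature_names = colnames(x), k_donors = k_donors,
                 n_cycles = n_cycles,
                 medians = apply(completed, 2L, stats::median)),
            class = "pmm_fit")
}

#' Impute a single validation row against the completed training data
#'
#' The row's missing cells are filled by PMM using only the fitted training
#' models and the completed training matrix; other validation rows are never
#' consulted, so rows can be imputed in any order with identical results.
#'
#' @param fit a `pmm_fit` from [pmm_impute()].
#' @param row named numeric vector (or 1-row matrix) with `NA` for missing.
#' @param seed integer seed.
#' @return the completed numeric vector.
#' @export
impute_validation_row <- function(fit, row, seed = NULL) {
  stopifnot(inherits(fit, "pmm_fit"))
  if (is.matrix(row) || is.data.frame(row)) row <- unlist(row[1L, ])
  row <- row[fit$feature_names]
  if (all(is.na(row)))
    stop("validation row has all features missing", call. = FALSE)
  miss_j <- which(is.na(row))
  if (!length(miss_j)) return(row)
  with_seed(seed, {
    # initialise like the training pass, then cycle through the stored models
    row[miss_j] <- fit$medians[miss_j]
    for (cycle in seq_len(fit$n_cycles)) {
      for (nm in names(fit$models)) {
        m <- fit$models[[nm]]
        if (!(m$j %in% miss_j)) next
        pred <- drop(c(1, row[-m$j]) %*% m$beta)
        d <- abs(m$donors_pred - pred)
        pool <- order(d)[seq_len(min(fit$k_donors, length(d)))]
        row[m$j] <- m$donors_val[pool[sample.int(length(pool), 1L)]]
      }
    }
    row
  })
}

#' Zero-variance, duplicate-correlation and anchor-correlation filter
#'
#' Drops zero-variance columns; among pairs with |Pearson r| above
#' `dup_threshold` keeps the earlier column in input order; drops non-anchor
#' columns whose |Pearson r| with any anchor exceeds `anchor_threshold`.
#' Anchors are always kept.
#'
#' @param x numeric matrix/data frame (no missing values).
#' @param dup_threshold near-duplicate correlation cutoff (default 0.99).
#' @param anchor_threshold anchor-correlation cutoff (default 0.80).
#' @param anchors feature names always kept and used as correlation anchors.
#' @return list with `keep` (surviving feature names, input order) and
#'   `dropped` (data frame: feature, reason).
#' @export
variance_correlation_filter <- function(x, dup_threshold = 0.99,
                                        anchor_threshold = 0.80,
                                        anchors = character()) {
  x <- as_feature_matrix(x)
  missing_anchor <- setdiff(anchors, colnames(x))
  if (length(missing_anchor))
    stop("anchor feature(s) not present: ",
         paste(missing_anchor, collapse = ", "), call. = FALSE)
  dropped <- list()
  nm <- colnames(x)
  vars <- apply(x, 2L, stats::var)
  zv <- vars == 0 & !(nm %in% anchors)
  for (f in nm[zv]) dropped[[f]] <- "zero variance"
  keep <- nm[!zv]
  xm <- x[, keep, drop = FALSE]
  if (ncol(xm) > 1L) {
    r <- suppressWarnings(abs(stats::cor(xm)))
    r[is.na(r)] <- 0
    # duplicates: later column of a too-correlated pair is dropped
    drop_dup <- rep(FALSE, ncol(xm))
    for (b in seq_len(ncol(xm))[-1L]) {
      if (drop_dup[b] || keep[b] %in% anchors) next
      for (a in seq_len(b - 1L)) {
        if (drop_dup[a]) next
        if (r[a, b] > dup_threshold) {
          drop_dup[b] <- TRUE
          dropped[[keep[b]]] <-
            sprintf("correlation %.4f with %s exceeds %.2f",
                    r[a, b], keep[a], dup_threshold)
          break
        }
      }
    }
    # anchor redundancy
    for (b in seq_len(ncol(xm))) {
      if (drop_dup[b] || keep[b] %in% anchors) next
      for (anc in intersect(anchors, keep)) {
        if (r[keep[b], anc] > anchor_threshold) {
          drop_dup[b] <- TRUE
          dropped[[keep[b]]] <-
            sprintf("correlation %.4f with anchor %s exceeds %.2f",
                    r[keep[b], anc], anc, anchor_threshold)
          break
        }
      }
    }
    keep <- keep[!drop_dup]
  }
  dropped_df <- if (length(dropped)) {
    data.frame(feature = names(dropped), reason = unlist(dropped),
               row.names = NULL)
  } else data.frame(feature = character(), reason = character())
  list(keep = keep, dropped = dropped_df)
}

#' Write a filter report as JSON
#' @param filter result of [variance_correlation_filter()].
#' @param path output file.
#' @export
write_filter_report <- function(filter, path) {
  jsonlite::write_json(filter, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' RReliefF feature importance for a continuous target
#'
#' The regression variant of ReliefF: importance of feature A estimates
#' P(diff. value of A | near instance with diff. prediction) minus
#' P(diff. value of A | near instance with same prediction). For each of
#' `n_iterations` randomly sampled instances, the `k_neighbors` nearest
#' instances under Manhattan distance contribute, with exponentially decaying
#' distance-rank influence weights, to the accumulators N_dC, N_dA and
#' N_dC&dA; weights are W = N_dC&dA / N_dC - (N_dA - N_dC&dA) / (m - N_dC).
#' Here the continuous target is the vector of null-model martingale
#' residuals, so features whose variation tracks excess hazard rank highest.
#'
#' @param x numeric feature matrix (standardized to [0, 1] upstream).
#' @param y continuous target (one value per row of `x`).
#' @param n_iterations sampled instances (default 1000).
#' @param k_neighbors nearest neighbours per instance (default 10).
#' @param sigma exponential rank-weighting scale (default 20).
#' @param seed integer seed.
#' @return named numeric vector of weights in [-1, 1], class
#'   `feature_importance`.
#' @export
rrelieff <- function(x, y, n_iterations = 1000L, k_neighbors = 10L,
                     sigma = 20, seed = NULL) {
  x <- as_feature_matrix(x)
  stopifnot(length(y) == nrow(x), !anyNA(x), !anyNA(y))
  n_iterations <- assert_count(n_iterations, "n_iterations", min = 1L)
  k_neighbors <- assert_count(k_neighbors, "k_neighbors", min = 1L)
  if (k_neighbors >= nrow(x))
    stop("k_neighbors must be smaller than the number of instances",
         call. = FALSE)
  w <- with_seed(seed,
                 rrelieff_cpp(x, as.numeric(y), n_iterations, k_neighbors,
                              sigma))
  names(w) <- colnames(x)
  class(w) <- "feature_importance"
  w
}

#' @export
print.feature_importance <- function(x, ...) {
  v <- unclass(x)
  print(sort(v, decreasing = TRUE))
  invisible(x)
}

#' Select the m features with the highest RReliefF weight
#' @param weights a `feature_importance` vector.
#' @param m number of features to keep (default 4).
#' @return character vector of feature names.
#' @export
select_top_m <- function(weights, m = 4L) {
  m <- assert_count(m, "m", min = 1L)
  v <- unclass(weights)
  names(sort(v, decreasing = TRUE))[seq_len(min(m, length(v)))]
}
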