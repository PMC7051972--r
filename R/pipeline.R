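#' Pipeline configuration for the cross-validated clustering experiment
#'
#' @param k_folds number of cross-validation folds (default 10).
#' @param k number of clusters (default 2).
#' @param consensus_runs k-medians runs per consensus clustering
#'   (default 1000).
#' @param subsample_fraction consensus subsampling fraction (default 0.8).
#' @param rrelieff_iterations RReliefF sampled instances (default
#'   1000); ignored when `rrelieff_m` is `NULL`.
#' @param rrelieff_m number of radiomic features kept by RReliefF (default
#'   4); `NULL` disables feature selection.
#' @param pmm_k PMM donor-pool size (default 5).
#' @param horizon evaluation horizon in months (default 60 = 5 years).
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(k_folds = 10L, k = 2L, consensus_runs = 1000L,
                            subsample_fraction = 0.8,
                            rrelieff_iterations = 1000L, rrelieff_m = 4L,
                            pmm_k = 5L, horizon = 60, seed = 1L) {
  k_folds <- assert_count(k_folds, "k_folds", min = 2L)
  structure(list(k_folds = k_folds, k = assert_count(k, "k", 1L),
                 consensus_runs = assert_count(consensus_runs,
                                               "consensus_runs", 1L),
                 subsample_fraction = subsample_fraction,
                 rrelieff_iterations = rrelieff_iterations,
                 rrelieff_m = if (is.null(rrelieff_m)) NULL
                              else assert_count(rrelieff_m, "rrelieff_m", 1L),
                 pmm_k = assert_count(pmm_k, "pmm_k", 1L),
                 horizon = horizon, seed = as.integer(seed)),
            class = "pipeline_config")
}

# seeded uniform random partition into k folds (no stratification)
make_folds <- function(n, k_folds, seed = NULL) {
  with_seed(seed, {
    fold <- rep(seq_len(k_folds), length.out = n)
    sample(fold)
  })
}

# one fold of the supervised-scaling pipeline; returns aligned validation
# labels for both the scaled and standardization-only branches
run_fold <- function(cohort, train_idx, valid_idx, config, fold_seed,
                     reference = NULL) {
  x <- as.matrix(cohort$features)
  xtr_raw <- x[train_idx, , drop = FALSE]

  # impute training, then each validation row individually against training
  imp <- pmm_impute(xtr_raw, k_donors = config$pmm_k,
                    seed = derive_seed(fold_seed, 11L))
  xtr <- imp$completed
  xva <- t(vapply(seq_along(valid_idx), function(i)
    impute_validation_row(imp, x[valid_idx[i], ],
                          seed = derive_seed(fold_seed, 100L + i)),
    numeric(ncol(x))))
  colnames(xva) <- colnames(x)

  std <- minmax_standardize(xtr)
  ztr <- std$values
  zva <- apply_standardization(std, xva)

  res <- null_martingale_residuals(cohort$time[train_idx],
                                   cohort$event[train_idx])

  keep <- colnames(ztr)
  if (!is.null(config$rrelieff_m) && !is.null(cohort$roles)) {
    rad <- intersect(keep, cohort$roles$feature[cohort$roles$role ==
                                                  "radiomic"])
    if (length(rad) > config$rrelieff_m) {
      w <- rrelieff(ztr[, rad, drop = FALSE], res,
                    n_iterations = config$rrelieff_iterations,
                    seed = derive_seed(fold_seed, 12L))
      top <- select_top_m(w, config$rrelieff_m)
      keep <- c(setdiff(keep, rad), top)
      keep <- colnames(ztr)[colnames(ztr) %in% keep]  # preserve order
    }
  }
  ztr <- ztr[, keep, drop = FALSE]
  zva <- zva[, keep, drop = FALSE]

  weights <- fit_scaling_weights(ztr, res)
  str_ <- apply_scaling(ztr, weights)
  sva <- apply_scaling(zva, weights)

  branch <- function(tr, va) {
    cc <- consensus_cluster(tr, k = config$k, n_runs = config$consensus_runs,
                            subsample_fraction = config$subsample_fraction,
                            seed = derive_seed(fold_seed, 13L))
    list(model = cc$model, valid = assign_to_clusters(cc$model, va))
  }
  scaled <- branch(str_, sva)
  standardized <- branch(ztr, zva)

  # align to the reference (fold 1) training labels on shared subjects
  if (!is.null(reference) && config$k == 2L) {
    align <- function(br, ref_lab, ref_idx) {
      shared <- intersect(train_idx, ref_idx)
      if (!length(shared)) return(br)
      lab <- match_fold_labels(
        br$model$labels, ref_lab,
        shared_index = list(labels = match(shared, train_idx),
                            reference = match(shared, ref_idx)))
      if (!identical(lab, br$model$labels)) {
        br$model$labels <- lab
        br$model$medians <- br$model$medians[2:1, , drop = FALSE]
        br$valid <- 3L - br$valid
      }
      br
    }
    scaled <- align(scaled, reference$scaled_labels, reference$train_idx)
    standardized <- align(standardized, reference$standardized_labels,
                          reference$train_idx)
  }
  list(scaled = scaled, standardized = standardized,
       weights = weights, residuals = res, features_used = keep,
       imputation = imp, standardization = std)
}

#' Run the cross-validated supervised-scaling clustering pipeline
#'
#' For each fold: PMM-impute the training subjects; impute each validation
#' row individually against the completed training data; min-max standardize
#' on training ranges; compute null-model martingale residuals on the
#' training outcomes; optionally keep the top-m radiomic features by
#' RReliefF; fit linear scaling weights on the residuals and scale the
#' space; consensus-cluster the training subjects; align the binary labels
#' to fold 1; and assign each validation subject to its nearest cluster
#' median. A standardization-only branch (identical but skipping the
#' scaling step) is produced for the "[Stand.]" comparison.
#'
#' @param cohort a `survival_cohort`.
#' @param config a [pipeline_config()].
#' @return list with `labels_scaled` and `labels_standardized` (per-subject
#'   validation cluster labels covering every subject exactly once),
#'   `fold` (fold id per subject), and `folds` (per-fold artifacts:
#'   scaling weights, selected features, training labels).
#' @export
run_cv <- function(cohort, config) {
  stopifnot(inherits(cohort, "survival_cohort"),
            inherits(config, "pipeline_config"))
  n <- nrow(cohort$features)
  if (floor(n / config$k_folds) * (config$k_folds - 1L) < config$k)
    stop("folds too small for the requested number of clusters",
         call. = FALSE)
  fold <- make_folds(n, config$k_folds, seed = derive_seed(config$seed, 0L))
  labels_scaled <- integer(n)
  labels_standardized <- integer(n)
  artifacts <- vector("list", config$k_folds)
  reference <- NULL
  for (f in seq_len(config$k_folds)) {
    valid_idx <- which(fold == f)
    train_idx <- which(fold != f)
    fr <- run_fold(cohort, train_idx, valid_idx, config,
                   fold_seed = derive_seed(config$seed, f), reference)
    if (f == 1L)
      reference <- list(train_idx = train_idx,
                        scaled_labels = fr$scaled$model$labels,
                        standardized_labels = fr$standardized$model$labels)
    labels_scaled[valid_idx] <- fr$scaled$valid
    labels_standardized[valid_idx] <- fr$standardized$valid
    artifacts[[f]] <- list(
      train_idx = train_idx, valid_idx = valid_idx,
      weights = fr$weights, features_used = fr$features_used,
      scaled_train_labels = fr$scaled$model$labels,
      standardized_train_labels = fr$standardized$model$labels,
      scaled_medians = fr$scaled$model$medians)
  }
  list(labels_scaled = labels_scaled,
       labels_standardized = labels_standardized,
       fold = fold, folds = artifacts)
}

fit_roster_model <- function(covars, x, time, event) {
  if (!length(covars)) cox_fit(NULL, time, event)
  else cox_fit(x[, covars, drop = FALSE], time, event)
}

#' Compare Cox models with and without the cluster labels
#'
#' Fits each roster model on the full cohort (the cluster
#' labels are those assigned to the validation samples at every fold) and
#' reports, against the configured baseline, the negated AIC/AICc
#' differences (positive = better than baseline), the likelihood-ratio test
#' p-value for nested pairs, and the hazard-ratio CI of the cluster label
#' where present. Predictive metrics (AUC, Brier, C-index) are computed
#' fold-wise on each fold's validation subjects from the full-data fit's
#' predicted event probabilities at the horizon, then aggregated as
#' mean +/- standard error; calibration is computed once over all subjects.
#'
#' @param cohort a `survival_cohort` (features must be complete; impute
#'   first with [pmm_impute()] if needed).
#' @param roster named list: for each model name, a character vector of
#'   feature column names; the tokens `"cluster_scaled"` and
#'   `"cluster_standardized"` refer to the CV-assigned labels.
#' @param cv result of [run_cv()] (or a list with `labels_scaled`,
#'   `labels_standardized`, `fold`).
#' @param config a [pipeline_config()] (horizon, folds).
#' @param baseline name of the baseline roster entry; `NULL` compares
#'   against the null (covariate-free) Cox model.
#' @return object of class `model_comparison`: data frame `table` with one
#'   row per model and the underlying `fits`.
#' @export
compare_models <- function(cohort, roster, cv, config, baseline = NULL) {
  stopifnot(inherits(cohort, "survival_cohort"), is.list(roster),
            !is.null(names(roster)), !anyDuplicated(names(roster)))
  x <- as.matrix(cohort$features)
  if (anyNA(x)) {
    x <- pmm_impute(x, k_donors = config$pmm_k,
                    seed = derive_seed(config$seed, 999L))$completed
  }
  x <- cbind(x,
             cluster_scaled = as.numeric(cv$labels_scaled == 2L),
             cluster_standardized = as.numeric(cv$labels_standardized == 2L))
  time <- cohort$time
  event <- cohort$event
  n <- length(time)

  base_covars <- if (is.null(baseline)) character() else roster[[baseline]]
  base_fit <- fit_roster_model(base_covars, x, time, event)
  base_ic <- aic_aicc(base_fit$loglik, base_fit$p, n)

  rows <- list()
  fits <- list()
  na_row <- function(nm, p) data.frame(
    model = nm, p = p, loglik = NA_real_, aic = NA_real_, aicc = NA_real_,
    neg_delta_aic = NA_real_, neg_delta_aicc = NA_real_, lrt_p = NA_real_,
    hr_lower = NA_real_, hr_upper = NA_real_, auc = NA_real_,
    auc_se = NA_real_, brier = NA_real_, c_index = NA_real_,
    c_index_se = NA_real_, calibration = NA_real_, row.names = NULL)
  for (nm in names(roster)) {
    covars <- roster[[nm]]
    fit <- tryCatch(fit_roster_model(covars, x, time, event),
                    error = function(e) {
                      warning("model '", nm, "' could not be fitted: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(fit)) {
      rows[[nm]] <- na_row(nm, length(covars))
      next
    }
    fits[[nm]] <- fit
    ic <- aic_aicc(fit$loglik, fit$p, n)
    nested <- all(base_covars %in% covars)
    lrt_p <- NA_real_
    if (nested && fit$p > base_fit$p) {
      lrt_p <- likelihood_ratio_test(base_fit$loglik, fit$loglik,
                                     fit$p - base_fit$p)$p.value
    } else if (identical(sort(covars), sort(base_covars))) {
      lrt_p <- 1
    }
    cl <- intersect(c("cluster_scaled", "cluster_standardized"), covars)
    hr_lo <- hr_hi <- NA_real_
    if (length(cl)) {
      hr_lo <- fit$hr[cl[1L], "lower"]
      hr_hi <- fit$hr[cl[1L], "upper"]
    }
    pred <- predict_event_prob(fit, x, config$horizon)
    per_fold_auc <- c()
    per_fold_c <- c()
    per_fold_brier <- c()
    for (f in sort(unique(cv$fold))) {
      idx <- which(cv$fold == f)
      auc_f <- tryCatch(auc_at_horizon(pred[idx], time[idx], event[idx],
                                       config$horizon), error = function(e)
                                         NA_real_)
      c_f <- tryCatch(concordance_index(pred[idx], time[idx], event[idx]),
                      error = function(e) NA_real_)
      b_f <- tryCatch(brier_ipcw(pred[idx], time[idx], event[idx],
                                 config$horizon), error = function(e)
                                   NA_real_)
      per_fold_auc <- c(per_fold_auc, auc_f)
      per_fold_c <- c(per_fold_c, c_f)
      per_fold_brier <- c(per_fold_brier, b_f)
    }
    cal <- tryCatch(nam_dagostino(pred, time, event, config$horizon)$statistic,
                    error = function(e) NA_real_)
    mse <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(c(NA_real_, NA_real_))
      c(mean(v), stats::sd(v) / sqrt(length(v)))
    }
    am <- mse(per_fold_auc); cm <- mse(per_fold_c)
    rows[[nm]] <- data.frame(
      model = nm, p = fit$p, loglik = fit$loglik,
      aic = ic$aic, aicc = ic$aicc,
      neg_delta_aic = base_ic$aic - ic$aic,
      neg_delta_aicc = base_ic$aicc - ic$aicc,
      lrt_p = lrt_p, hr_lower = hr_lo, hr_upper = hr_hi,
      auc = am[1L], auc_se = am[2L],
      brier = mean(per_fold_brier, na.rm = TRUE),
      c_index = cm[1L], c_index_se = cm[2L],
      calibration = cal, row.names = NULL)
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 baseline = baseline), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  base <- if (is.null(x$baseline)) "null model" else x$baseline
  cat("Cox model comparison (negated AIC differences vs ", base,
      "; positive = better):\n", sep = "")
  tab <- x$table
  tab$auc <- sprintf("%.4f +/- %.4f", tab$auc, tab$auc_se)
  tab$c_index <- sprintf("%.4f +/- %.4f", tab$c_index, tab$c_index_se)
  print(tab[, c("model", "p", "neg_delta_aic", "neg_delta_aicc", "lrt_p",
                "auc", "brier", "c_index", "calibration")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a model-comparison report as CSV/JSON
#' @param report a `model_comparison`.
#' @param path output path; extension picks the format (.csv or .json).
#' @export
write_comparison_report <- function(report, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(report$table, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
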