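#' Configuration for a synthetic right-censored cohort
#'
#' Describes the statistical structure of a simulated oropharyngeal-cancer-like
#' cohort: two latent risk groups with proportional exponential hazards,
#' binary clinical-style features, continuous "radiomic-like" features (a few
#' informative ones shifted between the latent groups, plus pure-noise ones),
#' independent exponential censoring calibrated to a target censoring
#' fraction, and MCAR missingness restricted to the continuous features.
#'
#' Defaults emulate a heavily censored oncology cohort:
#' roughly 640 subjects, ~79% censoring for overall survival, ~13%
#' missingness on the radiomic features, and a latent-group hazard ratio
#' on the 2-4 scale.
#'
#' @param n_subjects number of subjects (>= 20).
#' @param n_binary_features number of binary clinical-style features,
#'   independent of the latent groups.
#' @param n_continuous_features number of informative continuous features,
#'   mean-shifted by `group_separation` in latent group 2.
#' @param n_noise_features number of continuous noise features independent
#'   of the latent groups.
#' @param latent_hazard_ratio hazard ratio of latent group 2 vs group 1 (> 0).
#' @param baseline_event_rate exponential event rate (per month) in latent
#'   group 1, in (0, 1).
#' @param target_censoring_fraction desired overall fraction of censored
#'   subjects, in (0, 1) strictly; the censoring rate is solved numerically.
#' @param group_separation mean shift (in units of the unit feature standard
#'   deviation) of informative features in group 2; >= 0.
#' @param missing_rate MCAR missingness probability applied per cell to the
#'   continuous features, in [0, 1).
#' @param seed integer seed making generation fully reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 640L,
                          n_binary_features = 12L,
                          n_continuous_features = 4L,
                          n_noise_features = 8L,
                          latent_hazard_ratio = 3,
                          baseline_event_rate = 0.002,
                          target_censoring_fraction = 0.794,
                          group_separation = 2,
                          missing_rate = 0.131,
                          seed = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 20L)
  n_binary_features <- assert_count(n_binary_features, "n_binary_features")
  n_continuous_features <- assert_count(n_continuous_features,
                                        "n_continuous_features")
  n_noise_features <- assert_count(n_noise_features, "n_noise_features")
  stopifnot(latent_hazard_ratio > 0,
            baseline_event_rate > 0, baseline_event_rate < 1,
            group_separation >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (target_censoring_fraction <= 0 || target_censoring_fraction >= 1)
    stop("`target_censoring_fraction` must lie strictly in (0, 1): ",
         "a fraction of exactly 0 or 1 is unattainable with exponential ",
         "censoring", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 n_binary_features = n_binary_features,
                 n_continuous_features = n_continuous_features,
                 n_noise_features = n_noise_features,
                 latent_hazard_ratio = latent_hazard_ratio,
                 baseline_event_rate = baseline_event_rate,
                 target_censoring_fraction = target_censoring_fraction,
                 group_separation = group_separation,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# censoring rate so that P(C < T) = target under exponential event times
# mixed 50/50 over the two latent groups
solve_censoring_rate <- function(lambda1, lambda2, target) {
  f <- function(lc) 0.5 * lc / (lc + lambda1) + 0.5 * lc / (lc + lambda2) -
    target
  stats::uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-12)$root
}

#' Generate a synthetic right-censored cohort
#'
#' Subjects are split evenly between two latent risk groups. Event times are
#' exponential with rate `baseline_event_rate` in group 1 and
#' `latent_hazard_ratio` times that in group 2, so proportional hazards holds
#' by construction. Censoring times are independent exponential with rate
#' solved so the expected censoring fraction equals
#' `target_censoring_fraction`. Informative continuous features are
#' N(0, 1) in group 1 and N(`group_separation`, 1) in group 2; noise
#' continuous features are N(0, 1) and binary features Bernoulli with
#' per-feature prevalences drawn once from U(0.1, 0.9) — all independent of
#' the groups. MCAR missingness at `missing_rate` is then injected into the
#' continuous features.
#'
#' @param config a [cohort_config()].
#' @return an object of class `survival_cohort` with elements `features`
#'   (numeric data frame), `time`, `event` (outcome "os", months),
#'   `latent_group`, `missing_mask` (logical matrix), and `roles` (feature
#'   role table: clinical / radiomic, informative flag).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  with_seed(config$seed, {
    latent_group <- rep(1:2, length.out = n)
    lambda1 <- config$baseline_event_rate
    lambda2 <- lambda1 * config$latent_hazard_ratio
    rate <- ifelse(latent_group == 1L, lambda1, lambda2)
    t_event <- stats::rexp(n, rate)
    lc <- solve_censoring_rate(lambda1, lambda2,
                               config$target_censoring_fraction)
    t_cens <- stats::rexp(n, lc)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    feats <- list()
    roles <- list()
    if (config$n_binary_features > 0) {
      prev <- stats::runif(config$n_binary_features, 0.1, 0.9)
      for (j in seq_len(config$n_binary_features)) {
        nm <- sprintf("clin_%02d", j)
        feats[[nm]] <- stats::rbinom(n, 1L, prev[j])
        roles[[nm]] <- c("clinical", FALSE)
      }
    }
    shift <- ifelse(latent_group == 2L, config$group_separation, 0)
    if (config$n_continuous_features > 0) {
      for (j in seq_len(config$n_continuous_features)) {
        nm <- sprintf("rad_%02d", j)
        feats[[nm]] <- stats::rnorm(n) + shift
        roles[[nm]] <- c("radiomic", TRUE)
      }
    }
    if (config$n_noise_features > 0) {
      for (j in seq_len(config$n_noise_features)) {
        nm <- sprintf("rad_%02d", config$n_continuous_features + j)
        feats[[nm]] <- stats::rnorm(n)
        roles[[nm]] <- c("radiomic", FALSE)
      }
    }
    features <- as.data.frame(feats)
    roles <- data.frame(feature = names(roles),
                        role = vapply(roles, `[`, "", 1L),
                        informative = vapply(roles, `[`, "", 2L) == "TRUE",
                        row.names = NULL)
    cohort <- new_survival_cohort(features, time, event, latent_group, roles)
    if (config$missing_rate > 0) {
      cont_cols <- roles$feature[roles$role == "radiomic"]
      cohort <- inject_missingness(cohort, cont_cols, config$missing_rate,
                                   seed = derive_seed(config$seed, 1L))
    }
    cohort
  })
}

new_survival_cohort <- function(features, time, event, latent_group = NULL,
                                roles = NULL, missing_mask = NULL) {
  stopifnot(is.data.frame(features), length(time) == nrow(features),
            length(event) == nrow(features))
  if (any(is.na(time)) || any(is.na(event)))
    stop("subjects with missing follow-up time or event status must be ",
         "discarded before constructing a cohort", call. = FALSE)
  stopifnot(all(time >= 0), all(event %in% c(0L, 1L)))
  if (is.null(missing_mask)) {
    missing_mask <- is.na(as.matrix(features))
  }
  dimnames(missing_mask) <- list(NULL, names(features))
  structure(list(features = features, time = as.numeric(time),
                 event = as.integer(event),
                 latent_group = latent_group, roles = roles,
                 missing_mask = missing_mask),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d subjects, %d features\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  events: %d (censoring fraction %.3f)\n", sum(x$event),
              1 - mean(x$event)))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(x$missing_mask),
              100 * mean(x$missing_mask)))
  if (!is.null(x$latent_group))
    cat("  latent ground-truth groups present\n")
  invisible(x)
}

#' Inject MCAR missingness into selected feature columns
#'
#' Each targeted cell is independently masked (set to `NA`, recorded in the
#' missingness mask) with probability `rate`. Follow-up time and event status
#' are never masked.
#'
#' @param cohort a `survival_cohort`.
#' @param columns feature column names to target.
#' @param rate per-cell masking probability in [0, 1).
#' @param seed integer seed.
#' @return the cohort with updated `features` and `missing_mask`.
#' @export
inject_missingness <- function(cohort, columns, rate, seed = NULL) {
  stopifnot(inherits(cohort, "survival_cohort"), rate >= 0, rate < 1)
  unknown <- setdiff(columns, names(cohort$features))
  if (length(unknown))
    stop("unknown column name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (rate == 0 || length(columns) == 0) return(cohort)
  with_seed(seed, {
    n <- nrow(cohort$features)
    for (cl in columns) {
      hit <- stats::runif(n) < rate
      cohort$features[[cl]][hit] <- NA_real_
      cohort$missing_mask[, cl] <- cohort$missing_mask[, cl] | hit
    }
  })
  cohort
}

#' Write / read a cohort as plain CSV
#'
#' Columns are `time_os`, `event_os`, optional `latent_group`, then the
#' features; missing cells are written empty.
#'
#' @param cohort a `survival_cohort`.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `survival_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- data.frame(time_os = cohort$time, event_os = cohort$event)
  if (!is.null(cohort$latent_group)) df$latent_group <- cohort$latent_group
  df <- cbind(df, cohort$features)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  stopifnot(all(c("time_os", "event_os") %in% names(df)))
  lg <- if ("latent_group" %in% names(df)) df$latent_group else NULL
  feat_cols <- setdiff(names(df), c("time_os", "event_os", "latent_group"))
  new_survival_cohort(df[feat_cols], df$time_os, df$event_os,
                      latent_group = lg)
}
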