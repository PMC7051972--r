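#' Akaike information criterion and its small-sample correction
#'
#' AIC = 2p - 2 lnL; AICc = AIC + (2p^2 + 2p) / (n - p - 1). A negated
#' difference (-dAIC) of at least 3 against a baseline is treated as a
#' meaningful improvement.
#'
#' @param lnL maximized log-likelihood.
#' @param p number of estimated parameters.
#' @param n number of subjects.
#' @return list with `aic` and `aicc`.
#' @export
aic_aicc <- function(lnL, p, n) {
  p <- assert_count(p, "p")
  n <- assert_count(n, "n", min = 1L)
  aic <- 2 * p - 2 * lnL
  if (n <= p + 1L)
    stop("AICc undefined: n must exceed p + 1", call. = FALSE)
  list(aic = aic, aicc = aic + (2 * p^2 + 2 * p) / (n - p - 1))
}

#' Is a negated AIC difference meaningful?
#' @param neg_delta_aic baseline AIC minus model AIC (positive = better).
#' @return logical; TRUE when the improvement is at least 3.
#' @export
aic_meaningful <- function(neg_delta_aic) neg_delta_aic >= 3

#' Likelihood-ratio test between nested models
#'
#' Statistic -2 (lnL_null - lnL_alt), chi-square with `df` equal to the
#' difference in estimated parameters.
#'
#' @param lnL_null log-likelihood of the simpler model.
#' @param lnL_alt log-likelihood of the richer model.
#' @param df difference in parameter counts (>= 1).
#' @param tol tolerance for a numerically negative statistic.
#' @return list with `statistic` and `p.value`.
#' @export
likelihood_ratio_test <- function(lnL_null, lnL_alt, df, tol = 1e-8) {
  df <- assert_count(df, "df", min = 1L)
  stat <- -2 * (lnL_null - lnL_alt)
  if (stat < -tol)
    stop("alternative log-likelihood is below the null beyond tolerance; ",
         "models are not nested as given", call. = FALSE)
  stat <- max(stat, 0)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Concordance index with censoring-aware pair evaluability
#'
#' Pairs are enumerated and classified: both uncensored -> evaluable; both
#' censored -> not evaluable; one censored -> evaluable only if the censored
#' survival time is greater than the uncensored one. A pair is concordant
#' when the subject with the higher risk score has the shorter uncensored
#' survival; tied risk scores count 0.5. Time ties between an event and a
#' censoring treat the event as occurring first.
#'
#' @param risk numeric risk scores (higher = higher risk).
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(risk, time, event) {
  check_outcomes(time, event)
  stopifnot(length(risk) == length(time))
  n <- length(risk)
  concordant <- 0
  evaluable <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      di <- event[i]; dj <- event[j]
      if (di == 0L && dj == 0L) next
      # orient the pair so `a` is the earlier-failing / uncensored reference
      if (di == 1L && dj == 1L) {
        if (time[i] == time[j]) next # tied event times: not orderable
        a <- if (time[i] < time[j]) i else j
        b <- if (time[i] < time[j]) j else i
      } else {
        ev <- if (di == 1L) i else j
        ce <- if (di == 1L) j else i
        if (time[ce] < time[ev]) next  # censored strictly before the event
        a <- ev
        b <- ce
      }
      evaluable <- evaluable + 1
      if (risk[a] > risk[b]) concordant <- concordant + 1
      else if (risk[a] == risk[b]) concordant <- concordant + 0.5
    }
  }
  if (evaluable == 0) stop("no evaluable pairs", call. = FALSE)
  concordant / evaluable
}

# Kaplan-Meier estimator of the censoring distribution G (events and
# censorings swapped), evaluated left-continuously: G(t-) for IPCW weights
censoring_km <- function(time, event) {
  kaplan_meier(time, 1L - event)
}

eval_censoring_surv <- function(G, t, left = TRUE) {
  if (!length(G$time)) return(rep(1, length(t)))
  tt <- if (left) t - .Machine$double.eps^0.5 * pmax(1, abs(t)) else t
  idx <- findInterval(tt, G$time)
  c(1, G$surv)[idx + 1L]
}

#' IPCW Brier score at a horizon
#'
#' Weighted mean squared difference between predicted event probabilities by
#' the horizon and the observed event-by-horizon status. Subjects with an
#' observed event before the horizon get weight 1/G(t_i-), subjects still at
#' risk past the horizon 1/G(horizon), and subjects censored before the
#' horizon weight 0, where G is the Kaplan-Meier estimate of the censoring
#' distribution. Without censoring the score is the plain Brier score: 0.25
#' for a constant 0.5 prediction, 0 for perfect predictions.
#'
#' @param pred predicted event probabilities by `horizon`, in [0, 1].
#' @param time,event follow-up times and 0/1 event indicators.
#' @param horizon evaluation horizon (default 60 months, i.e. 5 years).
#' @return the Brier score.
#' @export
brier_ipcw <- function(pred, time, event, horizon = 60) {
  check_outcomes(time, event)
  stopifnot(length(pred) == length(time), horizon > 0,
            all(pred >= 0 & pred <= 1))
  G <- censoring_km(time, event)
  w <- numeric(length(time))
  status <- numeric(length(time))
  ev_before <- time <= horizon & event == 1L
  at_risk <- time > horizon
  Gt <- eval_censoring_surv(G, time, left = TRUE)
  Gh <- eval_censoring_surv(G, horizon, left = FALSE)
  if (any(ev_before & Gt == 0) || (any(at_risk) && Gh == 0))
    stop("censoring survival estimate is zero at a needed time",
         call. = FALSE)
  w[ev_before] <- 1 / Gt[ev_before]
  w[at_risk] <- 1 / Gh
  status[ev_before] <- 1
  mean(w * (status - pred)^2)
}

#' IPCW cumulative/dynamic AUC at a horizon
#'
#' Cases are subjects with an observed event by the horizon (weight
#' 1/G(t_i-)); controls are subjects still at risk past it (weight
#' 1/G(horizon)). The AUC is the weighted probability that a case receives a
#' higher predicted risk than a control, ties counting 0.5. Without
#' censoring this reduces to the Mann-Whitney statistic between the two
#' status groups.
#'
#' @inheritParams brier_ipcw
#' @param pred predicted risk (event probability by the horizon or any
#'   monotone risk score).
#' @return AUC in [0, 1].
#' @export
auc_at_horizon <- function(pred, time, event, horizon = 60) {
  check_outcomes(time, event)
  stopifnot(length(pred) == length(time), horizon > 0)
  cases <- which(time <= horizon & event == 1L)
  controls <- which(time > horizon)
  if (!length(cases) || !length(controls))
    stop("need at least one case and one control at the horizon",
         call. = FALSE)
  G <- censoring_km(time, event)
  wi <- 1 / eval_censoring_surv(G, time[cases], left = TRUE)
  wj <- rep(1 / eval_censoring_surv(G, horizon, left = FALSE),
            length(controls))
  cmp <- outer(pred[cases], pred[controls],
               function(a, b) (a > b) + 0.5 * (a == b))
  wmat <- outer(wi, wj)
  sum(wmat * cmp) / sum(wmat)
}

#' Nam-D'Agostino calibration statistic
#'
#' Subjects are binned by deciles (by default) of predicted risk; per bin
#' the observed event proportion by the horizon is 1 minus the
#' within-bin Kaplan-Meier survival at the horizon and the expected
#' proportion is the mean predicted risk. The statistic is
#' sum n_d (O_d - E_d)^2 / (E_d (1 - E_d)), approximately chi-square with
#' (bins - 2) degrees of freedom — 8 for deciles.
#'
#' @inheritParams brier_ipcw
#' @param n_bins number of risk bins (default 10, i.e. deciles).
#' @return list with `statistic`, `df`, `p.value`, and the per-bin table.
#' @export
nam_dagostino <- function(pred, time, event, horizon = 60, n_bins = 10L) {
  check_outcomes(time, event)
  stopifnot(length(pred) == length(time), horizon > 0)
  n_bins <- assert_count(n_bins, "n_bins", min = 2L)
  if (length(pred) < 2L * n_bins)
    stop("too few subjects for ", n_bins, " calibration bins", call. = FALSE)
  qs <- stats::quantile(pred, probs = seq(0, 1, length.out = n_bins + 1L),
                        type = 7)
  bins <- cut(pred, breaks = unique(qs), include.lowest = TRUE)
  stat <- 0
  tab <- data.frame()
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (!length(idx)) next
    km <- kaplan_meier(time[idx], event[idx])
    surv_h <- eval_step(km, horizon, values = km$surv, before = 1)
    O <- 1 - surv_h
    E <- mean(pred[idx])
    if (E <= 0 || E >= 1)
      stop("a calibration bin has mean predicted risk of 0 or 1",
           call. = FALSE)
    stat <- stat + length(idx) * (O - E)^2 / (E * (1 - E))
    tab <- rbind(tab, data.frame(bin = b, n = length(idx),
                                 observed = O, expected = E))
  }
  df <- n_bins - 2L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE), bins = tab)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected pair-counting agreement from the
#' contingency table: 1 for identical partitions, about 0 at chance level.
#'
#' @param labels_a,labels_b partition labels (equal length, any type).
#' @return the ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!length(labels_a) || length(labels_a) != length(labels_b))
    stop("partitions must be non-empty and of equal length", call. = FALSE)
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}
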