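#' Nelson-Aalen estimator of the cumulative hazard
#'
#' At each distinct event time s the estimate jumps by d_s / n_s, where d_s
#' is the number of events at s and n_s the number of subjects still at risk
#' (t_i >= s). This is the baseline cumulative hazard of a covariate-free
#' (null) Cox model and feeds the null-model martingale residuals.
#'
#' @param time nonnegative follow-up times (months).
#' @param event 0/1 event indicators (1 = event observed).
#' @return object of class `hazard_step`: right-continuous step function
#'   with `time` (jump times) and `cumhaz` values; value before the first
#'   jump is 0.
#' @export
nelson_aalen <- function(time, event) {
  check_outcomes(time, event)
  ev_times <- sort(unique(time[event == 1L]))
  if (!length(ev_times))
    return(structure(list(time = numeric(), cumhaz = numeric()),
                     class = "hazard_step"))
  d <- vapply(ev_times, function(s) sum(time == s & event == 1L), 0)
  n_risk <- vapply(ev_times, function(s) sum(time >= s), 0)
  structure(list(time = ev_times, cumhaz = cumsum(d / n_risk)),
            class = "hazard_step")
}

#' Kaplan-Meier product-limit estimator of survival
#'
#' @inheritParams nelson_aalen
#' @return object of class `survival_step` with `time` (event times),
#'   `surv` (survival just after each event time), and `n_risk`.
#' @export
kaplan_meier <- function(time, event) {
  check_outcomes(time, event)
  ev_times <- sort(unique(time[event == 1L]))
  if (!length(ev_times))
    return(structure(list(time = numeric(), surv = numeric(),
                          n_risk = numeric()), class = "survival_step"))
  d <- vapply(ev_times, function(s) sum(time == s & event == 1L), 0)
  n_risk <- vapply(ev_times, function(s) sum(time >= s), 0)
  structure(list(time = ev_times, surv = cumprod(1 - d / n_risk),
                 n_risk = n_risk),
            class = "survival_step")
}

check_outcomes <- function(time, event) {
  if (length(time) < 1L) stop("at least one subject required", call. = FALSE)
  stopifnot(length(time) == length(event))
  if (any(is.na(time)) || any(is.na(event)))
    stop("missing follow-up time or event status", call. = FALSE)
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  invisible(NULL)
}

# evaluate a step function (0 before first jump) at times t
eval_step <- function(sf, t, values = NULL, before = 0) {
  if (is.null(values)) values <- sf$cumhaz
  idx <- findInterval(t, sf$time)
  out <- c(before, values)[idx + 1L]
  out
}

#' Null-model martingale residuals
#'
#' For a Cox model with no covariates the martingale residual of subject i
#' reduces to the observed event count minus the Nelson-Aalen cumulative
#' hazard at the follow-up time: M_i = delta_i - Lambda-hat(t_i). Residuals
#' lie in (-Inf, +1] and, for the null model evaluated on its own data, sum
#' to zero exactly. They serve as the continuous proxy outcome for
#' supervised scaling: a positive residual marks a subject who failed
#' earlier than the cohort's aggregate hazard predicts.
#'
#' @inheritParams nelson_aalen
#' @return numeric vector of residuals, one per subject.
#' @export
null_martingale_residuals <- function(time, event) {
  na <- nelson_aalen(time, event)
  event - eval_step(na, time)
}

#' Log-rank test for equality of survival across groups
#'
#' Standard observed-minus-expected statistic; the null distribution is
#' chi-square with (number of groups - 1) degrees of freedom.
#'
#' @inheritParams nelson_aalen
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  check_outcomes(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("log-rank needs at least two non-empty groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron handling of tied event
#' times. A null fit (no covariates) returns the partial log-likelihood at
#' beta = 0 with zero estimated parameters.
#'
#' @param x covariate matrix / data frame, or `NULL` for the null model.
#' @inheritParams nelson_aalen
#' @return object of class `cox_fit`: `coefficients`, `loglik` (at the
#'   maximum), `loglik_null`, `var` (covariance of beta), `hr` (hazard
#'   ratios with 95% CIs), `p` (number of estimated parameters), `n`,
#'   `n_events`, and `breslow` (baseline cumulative hazard step function).
#' @export
cox_fit <- function(x, time, event) {
  check_outcomes(time, event)
  if (is.null(x) || NCOL(x) == 0L) {
    fit <- survival::coxph(survival::Surv(time, event) ~ 1)
    ll <- fit$loglik[1L]
    bh <- survival::basehaz(fit, centered = FALSE)
    return(structure(list(coefficients = numeric(), loglik = ll,
                          loglik_null = ll,
                          var = matrix(numeric(), 0, 0),
                          hr = data.frame(hr = numeric(), lower = numeric(),
                                          upper = numeric()),
                          p = 0L, n = length(time), n_events = sum(event),
                          breslow = structure(list(time = bh$time,
                                                   cumhaz = bh$hazard),
                                              class = "hazard_step")),
                     class = "cox_fit"))
  }
  x <- as_feature_matrix(x)
  if (anyNA(x)) stop("missing covariate values", call. = FALSE)
  const <- apply(x, 2L, function(v) length(unique(v)) == 1L)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x,
                    ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("beta may be infinite|did not converge", conditionMessage(w)))
        stop("Cox fit did not converge; monotone likelihood (complete ",
             "separation of a covariate) is the likely cause", call. = FALSE)
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ x,
                                       ties = "efron"))
    })
  beta <- stats::coef(fit)
  names(beta) <- colnames(x)
  if (any(is.na(beta)))
    stop("rank-deficient covariate matrix; aliased: ",
         paste(colnames(x)[is.na(beta)], collapse = ", "), call. = FALSE)
  se <- sqrt(diag(fit$var))
  hr <- data.frame(hr = exp(beta),
                   lower = exp(beta - 1.96 * se),
                   upper = exp(beta + 1.96 * se),
                   row.names = colnames(x))
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(coefficients = beta, loglik = fit$loglik[2L],
                 loglik_null = fit$loglik[1L], var = fit$var, hr = hr,
                 p = length(beta), n = length(time), n_events = sum(event),
                 breslow = structure(list(time = bh$time, cumhaz = bh$hazard),
                                     class = "hazard_step")),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d, p = %d, lnL = %.4f\n",
              x$n, x$n_events, x$p, x$loglik))
  if (x$p > 0) print(cbind(beta = x$coefficients, x$hr))
  invisible(x)
}

#' Predicted event probability by a horizon from a Cox fit
#'
#' Uses the Breslow baseline cumulative hazard: the probability of an event
#' by `horizon` for a subject with linear predictor eta is
#' 1 - exp(-Lambda0(horizon))^exp(eta).
#'
#' @param fit a `cox_fit`.
#' @param x covariate matrix for the subjects to predict (NULL for a null
#'   model).
#' @param horizon time horizon (months).
#' @return vector of event probabilities in [0, 1].
#' @export
predict_event_prob <- function(fit, x, horizon) {
  stopifnot(inherits(fit, "cox_fit"), horizon > 0)
  H0 <- eval_step(fit$breslow, horizon)
  eta <- if (fit$p == 0L) {
    n <- if (is.null(x)) fit$n else NROW(x)
    rep(0, n)
  } else {
    x <- as_feature_matrix(x)[, names(fit$coefficients), drop = FALSE]
    drop(x %*% fit$coefficients)
  }
  1 - exp(-H0 * exp(eta))
}

#' Export a Kaplan-Meier curve as a data frame (for CSV writing)
#' @param km a `survival_step` from [kaplan_meier()].
#' @return data frame with time, survival and number at risk.
#' @export
km_as_table <- function(km) {
  stopifnot(inherits(km, "survival_step"))
  data.frame(time = km$time, survival = km$surv, n_risk = km$n_risk)
}
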