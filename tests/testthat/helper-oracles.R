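# independent brute-force oracles used to check the implementations

# concordance by direct pair enumeration of the censoring-aware rules,
# written vectorized (outer products) so it shares no code with the
# implementation's loop
oracle_cindex <- function(risk, time, event) {
  n <- length(risk)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  both_ev <- event[i] == 1 & event[j] == 1
  mixed <- xor(event[i] == 1, event[j] == 1)
  # both uncensored: evaluable unless event times tie
  ev_both <- both_ev & time[i] != time[j]
  # mixed: evaluable iff censored time >= uncensored time (event first on tie)
  ev_t <- ifelse(event[i] == 1, time[i], time[j])
  ce_t <- ifelse(event[i] == 1, time[j], time[i])
  ev_mixed <- mixed & ce_t >= ev_t
  # subject failing first (the uncensored one for mixed pairs)
  first <- ifelse(both_ev, ifelse(time[i] < time[j], i, j),
                  ifelse(event[i] == 1, i, j))
  second <- ifelse(first == i, j, i)
  use <- ev_both | ev_mixed
  conc <- (risk[first] > risk[second]) + 0.5 * (risk[first] == risk[second])
  sum(conc[use]) / sum(use)
}

# adjusted Rand index by explicit pair counting
oracle_ari <- function(a, b) {
  n <- length(a)
  s_ab <- 0; s_a <- 0; s_b <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ai <- a[i] == a[j]; bi <- b[i] == b[j]
      if (ai && bi) s_ab <- s_ab + 1
      if (ai) s_a <- s_a + 1
      if (bi) s_b <- s_b + 1
    }
  }
  npairs <- n * (n - 1) / 2
  expected <- s_a * s_b / npairs
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(0)
  (s_ab - expected) / (max_index - expected)
}

# two-group log-rank by hand: observed minus expected with the
# hypergeometric variance at each distinct event time
oracle_logrank2 <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2L)
  ev_times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (s in ev_times) {
    at <- time >= s
    n <- sum(at)
    n1 <- sum(at & group == g[1L])
    d <- sum(time == s & event == 1)
    d1 <- sum(time == s & event == 1 & group == g[1L])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O1 - E1)^2 / V
  list(statistic = stat, p.value = pchisq(stat, 1, lower.tail = FALSE))
}

l1_cost <- function(x, labels) {
  total <- 0
  for (c in unique(labels)) {
    xc <- x[labels == c, , drop = FALSE]
    med <- apply(xc, 2L, median)
    total <- total + sum(abs(sweep(xc, 2L, med, "-")))
  }
  total
}

# exhaustive minimum total Manhattan cost over all 2-partitions
oracle_kmedians2_cost <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1L) - 1L)) {
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1L)]) # point 1 fixed
    lab <- lab[seq_len(n)]
    if (length(unique(lab)) < 2L) next
    best <- min(best, l1_cost(x, lab))
  }
  best
}

# small right-censored outcome generator for metric tests
sim_outcomes <- function(n, cens_rate = 1, event_rate = 1) {
  t_ev <- rexp(n, event_rate)
  t_ce <- rexp(n, cens_rate)
  list(time = pmin(t_ev, t_ce), event = as.integer(t_ev <= t_ce))
}

# labels of one full-sample k-medians run under the same seed the
# consensus wrapper would use (no subsample draw happens when the whole
# sample is used)
single_run_labels <- function(seed, x, k = 2L) {
  set.seed(seed)
  scaledclust:::kmedians_once_cpp(x, k, 100L)$labels
}
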