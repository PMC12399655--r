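# Independent oracles used across tests. These deliberately use naive
# enumeration / hand product-limit arithmetic, not the package's code paths.

# Harrell's C by exhaustive pair enumeration: a pair is usable when the
# earlier observed time is an event; concordant when that subject has the
# higher risk score; tied scores count one half.
oracle_harrell_c <- function(scores, times, events) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[i] == times[j]) next
      early <- if (times[i] < times[j]) i else j
      late <- if (times[i] < times[j]) j else i
      if (events[early] != 1) next
      den <- den + 1
      if (scores[early] > scores[late]) num <- num + 1
      else if (scores[early] == scores[late]) num <- num + 0.5
    }
  }
  num / den
}

# Hand product-limit estimator of the censoring survival G(t), evaluated
# with either the left limit (strict) or right-continuous value.
oracle_censor_surv <- function(times, events, t, strict = FALSE) {
  cens_times <- sort(unique(times[events == 0]))
  g <- 1
  for (ct in cens_times) {
    if ((strict && ct >= t) || (!strict && ct > t)) break
    at_risk <- sum(times >= ct)
    d <- sum(times == ct & events == 0)
    g <- g * (1 - d / at_risk)
  }
  g
}

# IPCW cumulative/dynamic AUC by brute-force weighted Mann-Whitney.
oracle_ipcw_auc <- function(scores, times, events, t) {
  case <- which(times <= t & events == 1)
  ctrl <- which(times > t)
  w_case <- sapply(times[case], function(ti)
    1 / oracle_censor_surv(times, events, ti, strict = TRUE))
  w_ctrl <- rep(1 / oracle_censor_surv(times, events, t), length(ctrl))
  num <- 0; den <- 0
  for (a in seq_along(case)) {
    for (b in seq_along(ctrl)) {
      si <- scores[case[a]]; sj <- scores[ctrl[b]]
      w <- w_case[a] * w_ctrl[b]
      num <- num + w * ((si > sj) + 0.5 * (si == sj))
      den <- den + w
    }
  }
  num / den
}

# Two-group log-rank by per-event-time hypergeometric accumulation.
oracle_logrank <- function(times, events, groups) {
  groups <- as.character(groups)
  g1 <- unique(groups)[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Quadrant labels by sorting scores and applying the strict-inequality rule.
oracle_quadrants <- function(intra, inter, q = 0.75) {
  thr_a <- stats::quantile(intra, q, type = 7)
  thr_e <- stats::quantile(inter, q, type = 7)
  sapply(seq_along(intra), function(i) {
    hi_a <- intra[i] > thr_a
    hi_e <- inter[i] > thr_e
    if (hi_a && hi_e) "Q1" else if (hi_e) "Q2" else if (hi_a) "Q4" else "Q3"
  })
}
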