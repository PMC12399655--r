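test_that("Kaplan-Meier steps match the hand product-limit", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # no events: the curve never drops
  km0 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # censoring removes from the risk set without a step
  kmc <- km_curve(c(1, 2, 3), c(1, 0, 1))
  ev <- kmc[kmc$n_event > 0, ]
  expect_equal(ev$surv, c(2 / 3, 0))
  expect_equal(ev$n_risk, c(3, 1))
  expect_error(km_curve(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank equals per-event hypergeometric accumulation", {
  times <- c(3, 5, 7, 2, 4, 8, 6, 9)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1)
  groups <- rep(c("a", "b"), each = 4)
  res <- logrank_test(times, events, groups)
  expect_equal(res$statistic, oracle_logrank(times, events, groups))
  expect_equal(res$df, 1)

  # duplicated data in two groups gives a near-zero statistic
  res0 <- logrank_test(rep(times, 2), rep(events, 2),
                       rep(c("x", "y"), each = 8))
  expect_lt(res0$statistic, 1e-10)
  expect_error(logrank_test(times, events, rep("a", 8)), "two groups")
})

test_that("Harrell's C matches brute-force pair enumeration", {
  set.seed(70)
  n <- 30
  times <- rexp(n, 0.1)
  events <- rbinom(n, 1, 0.7)
  scores <- rnorm(n)
  expect_equal(harrell_c(scores, times, events),
               oracle_harrell_c(scores, times, events))

  # perfect anti-ordering, no censoring
  t2 <- sort(rexp(20, 0.1))
  expect_equal(harrell_c(rev(seq_len(20)), t2, rep(1, 20)), 1)

  # independent scores hover at 1/2
  set.seed(71)
  tt <- rexp(4000, 0.1)
  expect_lt(abs(harrell_c(rnorm(4000), tt, rep(1, 4000)) - 0.5), 0.03)

  # complementary scores: C(s) + C(-s) = 1 when scores are distinct
  expect_equal(harrell_c(scores, times, events) +
                 harrell_c(-scores, times, events), 1)
})

test_that("IPCW AUC reduces to the empirical AUC without censoring", {
  set.seed(72)
  n <- 100
  times <- rexp(n, 0.1)
  scores <- -times + rnorm(n, 0, 5)
  t0 <- median(times)
  auc <- time_dependent_auc(scores, times, rep(1, n), t0)
  case <- times <= t0
  brute <- mean(outer(scores[case], scores[!case],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc$auc, brute)
  # invariant under strictly increasing transforms
  auc2 <- time_dependent_auc(exp(scores / 3), times, rep(1, n), t0)
  expect_equal(auc2$auc, auc$auc)
})

test_that("IPCW AUC matches the brute-force weighted Mann-Whitney", {
  set.seed(73)
  n <- 50
  times <- rexp(n, 0.15)
  cens <- runif(n, 0, 12)
  obs <- pmin(times, cens)
  events <- as.integer(times <= cens)
  scores <- -log(times) + rnorm(n, 0, 0.8)
  t0 <- unname(quantile(obs, 0.5))
  auc <- time_dependent_auc(scores, obs, events, t0)
  expect_equal(auc$auc, oracle_ipcw_auc(scores, obs, events, t0))

  # independent scores are uninformative
  set.seed(74)
  big_t <- rexp(3000, 0.15); big_c <- runif(3000, 0, 15)
  big_obs <- pmin(big_t, big_c); big_e <- as.integer(big_t <= big_c)
  a <- time_dependent_auc(rnorm(3000), big_obs, big_e, 5)
  expect_lt(abs(a$auc - 0.5), 0.04)
  expect_error(time_dependent_auc(scores, obs, events, 1e6), "at risk")
})

test_that("hazard-ratio pooling is the inverse-variance average", {
  rep5 <- pool_hazard_ratios(rep(0.4, 5), rep(0.3, 5))
  expect_equal(rep5$log_hr, 0.4)
  expect_equal(rep5$se, 0.3 / sqrt(5))

  two <- pool_hazard_ratios(c(0, 1), c(1, 1))
  expect_equal(two$log_hr, 0.5)

  # a near-infinite-variance study carries no weight
  three <- suppressWarnings(pool_hazard_ratios(c(0, 1, 50), c(1, 1, 1e6)))
  expect_equal(three$log_hr, 0.5, tolerance = 1e-6)
  expect_error(pool_hazard_ratios(c(0, 1), c(1, 0)), "positive")
})

test_that("survival-probability prediction matches KM for a null model and the exponential closed form", {
  set.seed(75)
  n <- 400
  times <- rexp(n, 0.2)
  cens <- runif(n, 0, 15)
  d <- data.frame(time = pmin(times, cens),
                  event = as.integer(times <= cens),
                  x = rnorm(n))
  null_fit <- survival::coxph(survival::Surv(time, event) ~ 1, data = d)
  t0 <- 4
  pred <- predict_survival_prob(null_fit, d[1:3, ], t0)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  km_at <- sf$surv[max(which(sf$time <= t0))]
  expect_equal(unique(round(pred$surv_prob, 10)),
               round(km_at, 10), tolerance = 0.02)

  # exponential data: S(t | x) = exp(-h0 t e^{beta x})
  h0 <- 0.2; beta <- 0.7
  x <- rnorm(n)
  t_ev <- rexp(n, h0 * exp(beta * x))
  d2 <- data.frame(time = t_ev, event = 1, x = x)
  fit2 <- survival::coxph(survival::Surv(time, event) ~ x, data = d2)
  newx <- data.frame(x = c(-1, 0, 1))
  p2 <- predict_survival_prob(fit2, newx, 3)
  closed <- exp(-h0 * 3 * exp(beta * newx$x))
  expect_equal(p2$surv_prob, closed, tolerance = 0.05, ignore_attr = TRUE)

  # an extreme negative linear predictor pushes survival toward 1
  p3 <- predict_survival_prob(fit2, data.frame(x = -12), 3)
  expect_gt(p3$surv_prob, 0.99)
  expect_warning(predict_survival_prob(fit2, newx, max(t_ev) + 10),
                 "beyond observed follow-up")
})

test_that("calibration collapses to the overall KM for a constant prediction", {
  set.seed(76)
  n <- 150
  d <- data.frame(time = rexp(n, 0.2), event = 1, x = rnorm(n))
  null_fit <- survival::coxph(survival::Surv(time, event) ~ 1, data = d)
  suppressWarnings(
    cal <- calibration_curve(null_fit, d, horizon = 3, n_boot = 20,
                             n_bins = 3))
  expect_equal(nrow(cal), 1)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  km_at <- sf$surv[max(which(sf$time <= 3))]
  expect_equal(cal$observed, km_at)
})

test_that("high-risk groups from planted effects show elevated hazard and concordance", {
  t <- sim_truth(n_genes = 20, n_prognostic = 2, beta = 0.8, seed = 77)
  sv <- gen_survival_cohort(t, 400, seed = 78)
  planted <- t$genes$gene[t$genes$beta != 0]
  model <- fit_cox_signature(sv$expr, sv$surv, planted)
  scores <- score_samples(model, sv$expr, "train")
  prof <- dichotomize(scores)
  d <- dplyr::inner_join(prof, sv$surv, by = "sample_id")
  fit <- cox_fit(data.frame(time = d$time, event = d$event,
                            high = as.integer(d$group == "high")), "high")
  expect_gt(fit$hr, 1)
  expect_gt(harrell_c(d$score, d$time, d$event), 0.5)
  # monotone in effect size: a weaker-effect cohort has lower concordance
  t_weak <- sim_truth(n_genes = 20, n_prognostic = 2, beta = 0.2, seed = 77)
  sv_w <- gen_survival_cohort(t_weak, 400, seed = 78)
  m_w <- fit_cox_signature(sv_w$expr, sv_w$surv, planted)
  s_w <- score_samples(m_w, sv_w$expr, "train")
  d_w <- dplyr::inner_join(s_w, sv_w$surv, by = "sample_id")
  expect_gt(harrell_c(d$score, d$time, d$event),
            harrell_c(d_w$score, d_w$time, d_w$event))
})
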