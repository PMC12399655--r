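#' Kaplan-Meier survival curves
#'
#' Product-limit estimate per group (or overall), returned as a tidy step
#' table. Censored subjects leave the risk set without producing a step.
#' Group medians (first time the curve reaches 0.5) are attached as an
#' attribute.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (0/1).
#' @param groups Optional group labels.
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, with a `medians` tibble attribute.
#' @export
km_curve <- function(times, events, groups = NULL) {
  if (any(times <= 0) || any(!is.finite(times))) {
    abort("All times must be positive and finite.")
  }
  if (is.null(groups)) groups <- rep("all", length(times))
  df <- data.frame(time = times, event = as.integer(events),
                   group = as.character(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(df$group), length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  out <- tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                n_event = sm$n.event, n_censor = sm$n.censor,
                surv = sm$surv)
  med <- summary(fit)$table
  if (is.null(dim(med))) med <- matrix(med, nrow = 1,
                                       dimnames = list("all", names(med)))
  attr(out, "medians") <- tibble(group = sub("^group=", "", rownames(med)),
                                 median = unname(med[, "median"]))
  out
}

#' Log-rank test across survival groups
#'
#' Standard observed-minus-expected statistic over hypergeometric variance
#' (1 degree of freedom for two groups).
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (0/1).
#' @param groups Group labels (>= 2 distinct).
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) {
    abort("Log-rank test needs at least two groups.")
  }
  if (sum(events) < 1) abort("Log-rank test needs at least one event.")
  df <- data.frame(time = times, event = as.integer(events), group = groups)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = k,
         p = stats::pchisq(sd$chisq, k, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for one or more predictors
#'
#' Partial-likelihood Newton fit with Efron tie handling. Returns a
#' broom-style coefficient table with Wald tests and hazard-ratio
#' confidence intervals.
#'
#' @param data Data frame with `time`, `event` and the predictor columns.
#' @param predictors Character vector of predictor column names.
#' @param adjust Optional covariate column names added to the model.
#' @param conf.level Confidence level (default 0.95).
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `hr`, `conf.low`, `conf.high`.
#' @export
cox_fit <- function(data, predictors, adjust = NULL, conf.level = 0.95) {
  vars <- c(predictors, adjust)
  if (!all(c("time", "event", vars) %in% names(data))) {
    abort("`data` must contain time, event and all predictor columns.")
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", vars), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron",
                         control = survival::coxph.control(
                           eps = 1e-9, iter.max = 50))
  s <- summary(fit, conf.int = conf.level)
  co <- s$coefficients
  ci <- s$conf.int
  tibble(
    term = rownames(co),
    estimate = unname(co[, "coef"]),
    std.error = unname(co[, "se(coef)"]),
    statistic = unname(co[, "z"]),
    p.value = unname(co[, "Pr(>|z|)"]),
    hr = unname(ci[, 1]),
    conf.low = unname(ci[, 3]),
    conf.high = unname(ci[, 4])
  )
}

#' Univariate Cox screen over all genes
#'
#' Iterates a univariate Cox fit over every gene in the expression matrix
#' and flags genes with Wald p below `alpha`. Genes whose fit fails
#' (separation, non-convergence) are reported with NA statistics and a
#' note, without aborting the screen.
#'
#' @param expr Gene x sample expression matrix.
#' @param surv Survival tibble with `sample_id`, `time`, `event`.
#' @param alpha Screening threshold (default 0.05).
#' @param adjust Optional covariate columns of `surv` to adjust for.
#' @return Tibble: `gene`, `estimate`, `hr`, `std.error`, `p`,
#'   `significant`, `note`.
#' @export
cox_screen <- function(expr, surv, alpha = 0.05, adjust = NULL) {
  m <- as_expr_matrix(expr)
  surv <- surv[match(colnames(m), surv$sample_id), , drop = FALSE]
  if (anyNA(surv$time)) abort("`surv` must cover every expression sample.")
  base <- data.frame(time = surv$time, event = surv$event)
  for (cv in adjust) base[[cv]] <- surv[[cv]]
  res <- purrr::map(rownames(m), function(gn) {
    d <- base
    d$x <- m[gn, ]
    out <- tryCatch({
      tab <- suppressWarnings(cox_fit(d, "x", adjust = adjust))
      row <- tab[tab$term == "x", ]
      if (!is.finite(row$std.error) || row$std.error > 100) {
        stop("unstable fit")
      }
      list(est = row$estimate, hr = row$hr, se = row$std.error,
           p = row$p.value, note = NA_character_)
    }, error = function(e) {
      list(est = NA_real_, hr = NA_real_, se = NA_real_, p = NA_real_,
           note = conditionMessage(e))
    })
    tibble(gene = gn, estimate = out$est, hr = out$hr,
           std.error = out$se, p = out$p, note = out$note)
  })
  res <- dplyr::bind_rows(res)
  dplyr::mutate(res, significant = !is.na(.data$p) & .data$p < alpha,
                .before = "note")
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the sample with the higher risk score
#' has the shorter observed survival; tied scores count one half, pairs
#' rendered unusable by censoring are excluded.
#'
#' @param scores Risk scores (higher = higher predicted risk).
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(scores, times, events) {
  if (length(scores) < 2) abort("Need at least 2 samples.")
  if (sum(events) < 1) abort("Need at least one event.")
  df <- data.frame(time = times, event = as.integer(events), x = scores)
  cc <- survival::concordance(survival::Surv(time, event) ~ x, data = df)
  n_usable <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (n_usable == 0) abort("No usable pairs under this censoring pattern.")
  # concordance() counts larger x with longer time as concordant; a risk
  # score predicts shorter time, so flip.
  1 - unname(cc$concordance)
}

# Kaplan-Meier estimate of the censoring survival G(t), as step arrays.
censoring_km <- function(times, events) {
  df <- data.frame(time = times, cens = 1 - as.integer(events))
  fit <- survival::survfit(survival::Surv(time, cens) ~ 1, data = df)
  list(time = fit$time, surv = fit$surv)
}

#' Time-dependent (cumulative/dynamic) AUC with IPCW
#'
#' Discrimination at horizon t between cases (event by t) and controls
#' (event-free past t), weighting observations by the inverse of the
#' Kaplan-Meier estimate of the censoring survival: cases by `1/G(T_i-)`,
#' controls by `1/G(t)`. With no censoring all weights are 1 and the result
#' is the empirical AUC of `{T <= t}` versus `{T > t}`; with a binary
#' uncensored response the same machinery yields the ordinary ROC AUC.
#'
#' @param scores Risk scores (higher = higher predicted risk).
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @param horizons One or more evaluation times.
#' @return Tibble: `horizon`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(scores, times, events, horizons) {
  events <- as.integer(events)
  G <- censoring_km(times, events)
  purrr::map_dfr(horizons, function(t) {
    case <- which(times <= t & events == 1)
    ctrl <- which(times > t)
    if (length(case) == 0) abort(sprintf("No events by horizon %s.", t))
    if (length(ctrl) == 0) abort(sprintf("No subjects at risk past %s.", t))
    w_case <- 1 / vapply(times[case], function(ti)
      step_surv_at(G$time, G$surv, ti, strict = TRUE), numeric(1))
    w_ctrl <- rep(1 / step_surv_at(G$time, G$surv, t, strict = FALSE),
                  length(ctrl))
    sc <- scores[case]; sj <- scores[ctrl]
    cmp <- outer(sc, sj, function(a, b) (a > b) + 0.5 * (a == b))
    num <- drop(w_case %*% cmp %*% w_ctrl)
    den <- sum(w_case) * sum(w_ctrl)
    tibble(horizon = t, auc = num / den,
           n_cases = length(case), n_controls = length(ctrl))
  })
}

#' Pool hazard ratios across cohorts by inverse-variance meta-analysis
#'
#' Fixed-effect (equal-effects) inverse-variance weighted mean of the
#' per-cohort log hazard ratios, with a random-effects (REML) alternative
#' behind `method`.
#'
#' @param log_hr Per-study log hazard ratios.
#' @param se Their standard errors (> 0).
#' @param method `"fixed"` (default) or `"random"`.
#' @param conf.level Confidence level (default 0.95).
#' @return One-row tibble: `k`, `log_hr`, `se`, `hr`, `conf.low`,
#'   `conf.high`, `p`, `method`.
#' @export
pool_hazard_ratios <- function(log_hr, se, method = c("fixed", "random"),
                               conf.level = 0.95) {
  method <- match.arg(method)
  if (length(log_hr) < 2 || length(se) != length(log_hr)) {
    abort("Need >= 2 studies with matching `log_hr` and `se`.")
  }
  if (any(se <= 0)) abort("All standard errors must be positive.")
  fit <- metafor::rma.uni(yi = log_hr, sei = se,
                          method = if (method == "fixed") "EE" else "REML",
                          level = conf.level * 100)
  tibble(k = length(log_hr), log_hr = as.numeric(fit$beta),
         se = fit$se, hr = exp(as.numeric(fit$beta)),
         conf.low = exp(fit$ci.lb), conf.high = exp(fit$ci.ub),
         p = fit$pval, method = method)
}

#' Predicted survival probabilities from a Cox model
#'
#' `S(t | x) = S0(t)^exp(lp(x))` with the Breslow baseline cumulative
#' hazard. Accepts either a `coxph` fit with a new-data frame, or an
#' `evosig_model` with an expression matrix (scored with training
#' standardization). Horizons beyond the observed follow-up are flagged as
#' extrapolation.
#'
#' @param model A `coxph` fit or an `evosig_model`.
#' @param newdata Data frame of covariates (coxph) or gene x sample
#'   expression matrix (evosig_model).
#' @param horizons Evaluation times.
#' @return Tibble: `sample_id`, `horizon`, `surv_prob`, `extrapolated`.
#' @export
predict_survival_prob <- function(model, newdata, horizons) {
  if (inherits(model, "evosig_model")) {
    m <- as_expr_matrix(newdata)
    z <- (m[model$genes, , drop = FALSE] - model$center) / model$scale
    nd <- as.data.frame(t(z))
    names(nd) <- model$genes
    ids <- colnames(m)
    fit <- model$fit
  } else if (inherits(model, "coxph")) {
    nd <- as.data.frame(newdata)
    ids <- if (!is.null(rownames(nd))) rownames(nd) else
      sprintf("S%04d", seq_len(nrow(nd)))
    fit <- model
  } else {
    abort("`model` must be a coxph fit or an evosig_model.")
  }
  sf <- survival::survfit(fit, newdata = nd, ctype = 1, stype = 2)
  t_max <- max(sf$time)
  surv <- rbind(sf$surv)  # time x newdata (or 1 x time when single subject)
  if (is.null(dim(sf$surv))) surv <- matrix(sf$surv, ncol = 1)
  extrap <- horizons > t_max
  if (any(extrap)) {
    warn(sprintf("Horizon(s) beyond observed follow-up (%.3g): %s",
                 t_max, paste(horizons[extrap], collapse = ", ")))
  }
  purrr::map_dfr(seq_along(horizons), function(j) {
    t <- horizons[j]
    probs <- vapply(seq_len(ncol(surv)), function(i)
      step_surv_at(sf$time, surv[, i], t), numeric(1))
    tibble(sample_id = ids, horizon = t, surv_prob = probs,
           extrapolated = extrap[j])
  })
}

#' Calibration of predicted survival probabilities with bootstrap optimism
#'
#' Bins the cohort by predicted survival at horizon t (quantile bins on the
#' original predictions), takes the Kaplan-Meier estimate at t within each
#' bin as the observed survival, and corrects for optimism by the standard
#' bootstrap-refit scheme: on each resample the model is refit, the
#' apparent per-bin calibration error on the resample is compared with the
#' refit model's error on the original cohort, and the mean difference is
#' subtracted from the apparent observed values. Percentile bands come from
#' the bootstrap distribution of the original-cohort error.
#'
#' @param fit A `coxph` model fitted on `data`.
#' @param data The data frame the model was fit on (must contain `time`,
#'   `event` and the model covariates).
#' @param horizon Evaluation time.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param n_bins Prediction bins (default 3; reduced with a warning when a
#'   bin would be empty).
#' @param conf.level Band level (default 0.95).
#' @return Tibble: `bin`, `n`, `predicted`, `observed`,
#'   `observed_corrected`, `conf.low`, `conf.high`.
#' @export
calibration_curve <- function(fit, data, horizon, n_boot = 1000, n_bins = 3,
                              conf.level = 0.95) {
  stopifnot(inherits(fit, "coxph"))
  if (sum(data$event & data$time <= horizon) < n_bins) {
    abort("Too few events before the horizon for the requested bins.")
  }
  pred <- predict_survival_prob(fit, data, horizon)$surv_prob

  make_bins <- function(p, k) {
    while (k > 1) {
      br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = k + 1)))
      if (length(br) >= 3) {
        bins <- cut(p, br, include.lowest = TRUE, labels = FALSE)
        if (all(tabulate(bins, max(bins)) > 0)) return(bins)
      }
      k <- k - 1
      warn(sprintf("Reducing calibration bins to %d (empty bin).", k))
    }
    rep(1L, length(p))
  }
  bins <- make_bins(pred, n_bins)
  k <- max(bins)

  km_at <- function(time, event, t) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1)
    step_surv_at(sf$time, sf$surv, t)
  }
  bin_table <- function(p, bins, time, event) {
    vapply(seq_len(max(bins)), function(b) {
      i <- bins == b
      c(pred = mean(p[i]), obs = km_at(time[i], event[i], horizon))
    }, numeric(2))
  }
  app <- bin_table(pred, bins, data$time, data$event)

  optimism <- matrix(NA_real_, n_boot, k)
  err_orig <- matrix(NA_real_, n_boot, k)
  fml <- stats::formula(fit)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(data), replace = TRUE)
    db <- data[idx, , drop = FALSE]
    fb <- tryCatch(survival::coxph(fml, data = db, ties = "efron"),
                   error = function(e) NULL)
    if (is.null(fb)) next
    pb <- tryCatch(predict_survival_prob(fb, db, horizon)$surv_prob,
                   error = function(e) NULL)
    po <- tryCatch(predict_survival_prob(fb, data, horizon)$surv_prob,
                   error = function(e) NULL)
    if (is.null(pb) || is.null(po)) next
    bb <- make_bins(pb, k)
    bo <- make_bins(po, k)
    tb <- tryCatch(bin_table(pb, bb, db$time, db$event),
                   error = function(e) NULL)
    to <- tryCatch(bin_table(po, bo, data$time, data$event),
                   error = function(e) NULL)
    if (is.null(tb) || is.null(to) || ncol(tb) != k || ncol(to) != k) next
    optimism[b, ] <- (tb["obs", ] - tb["pred", ]) - (to["obs", ] - to["pred", ])
    err_orig[b, ] <- to["obs", ] - to["pred", ]
  }
  opt <- colMeans(optimism, na.rm = TRUE)
  alpha2 <- (1 - conf.level) / 2
  lo <- apply(err_orig, 2, stats::quantile, probs = alpha2, na.rm = TRUE)
  hi <- apply(err_orig, 2, stats::quantile, probs = 1 - alpha2, na.rm = TRUE)
  tibble(
    bin = seq_len(k),
    n = tabulate(bins, k),
    predicted = unname(app["pred", ]),
    observed = unname(app["obs", ]),
    observed_corrected = unname(app["obs", ] - opt),
    conf.low = unname(app["pred", ] + lo),
    conf.high = unname(app["pred", ] + hi)
  )
}
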