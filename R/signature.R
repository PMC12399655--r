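#' Candidate gene set: three-way intersection
#'
#' Intersects the consensus evolution-related genes with the differentially
#' expressed genes and the survival-associated genes from the Cox screen.
#'
#' @param evo,de,surv Character vectors of gene identifiers.
#' @return Character vector present in all three sets.
#' @export
candidate_genes <- function(evo, de, surv) {
  Reduce(intersect, list(as.character(evo), as.character(de),
                         as.character(surv)))
}

#' Stability selection with L1-penalized Cox regression
#'
#' Repeatedly subsamples the cohort without replacement, fits a penalized
#' Cox model over the candidate genes on each subsample (penalty chosen by
#' internal cross-validated partial likelihood), and records which genes
#' receive nonzero coefficients. Genes selected in more than a fraction
#' `freq_min` of iterations form the stable set; the defaults mirror 1,000
#' subsamples with an 850-iteration cutoff. Per-iteration seeds are derived
#' deterministically from the master seed, so the run is reproducible and
#' iterations are order-independent.
#'
#' @param expr Gene x sample expression matrix (log scale).
#' @param surv Survival tibble with `sample_id`, `time`, `event` covering
#'   the matrix columns.
#' @param candidates Candidate genes, a subset of `rownames(expr)`.
#' @param n_iter Number of subsample iterations (default 1000).
#' @param freq_min Selection-frequency cutoff; a gene is kept when its
#'   frequency is strictly greater (default 0.85).
#' @param subsample_frac Fraction of samples drawn without replacement per
#'   iteration (default 0.8).
#' @param mixing Elastic-net mixing parameter passed to glmnet's `alpha`;
#'   1 (default) is the pure lasso.
#' @param nfolds Cross-validation folds inside each subsample (default 5).
#' @param penalty Which cross-validated penalty to use: `"lambda.1se"`
#'   (default; the sparser one-standard-error rule, which keeps spurious
#'   genes out of the per-iteration support) or `"lambda.min"`.
#' @param seed Master seed.
#' @param max_retries Redraw attempts when a subsample carries too few
#'   events to cross-validate (default 10).
#' @return Tibble: `gene`, `frequency`, `selected`, ordered by decreasing
#'   frequency, with the run parameters in attribute `params` and the
#'   selected genes in attribute `selected`.
#' @export
stability_select <- function(expr, surv, candidates, n_iter = 1000,
                             freq_min = 0.85, subsample_frac = 0.8,
                             mixing = 1, nfolds = 5,
                             penalty = c("lambda.1se", "lambda.min"),
                             seed = 1, max_retries = 10) {
  penalty <- match.arg(penalty)
  m <- as_expr_matrix(expr)
  candidates <- as.character(candidates)
  if (!all(candidates %in% rownames(m))) {
    abort("All `candidates` must be rows of `expr`.")
  }
  if (length(candidates) < 2) abort("Need at least 2 candidate genes.")
  surv <- surv[match(colnames(m), surv$sample_id), , drop = FALSE]
  if (anyNA(surv$time)) abort("`surv` must cover every expression sample.")
  x <- t(m[candidates, , drop = FALSE])
  y <- survival::Surv(surv$time, surv$event)
  n <- nrow(x)
  n_sub <- max(2L, floor(subsample_frac * n))

  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  hits <- stats::setNames(numeric(length(candidates)), candidates)
  n_redraws <- 0L
  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    for (attempt in seq_len(max_retries + 1L)) {
      idx <- sample.int(n, n_sub)
      if (sum(surv$event[idx]) >= nfolds) break
      n_redraws <- n_redraws + 1L
      if (attempt > max_retries) {
        abort("Could not draw a subsample with enough events.")
      }
    }
    # glmnet occasionally warns about numerical trouble at the smallest
    # lambdas; the solutions on the usable part of the path are returned
    cvfit <- suppressWarnings(
      glmnet::cv.glmnet(x[idx, , drop = FALSE], y[idx],
                        family = "cox", alpha = mixing,
                        nfolds = nfolds, standardize = TRUE))
    cf <- as.matrix(stats::coef(cvfit, s = penalty))
    nz <- rownames(cf)[cf[, 1] != 0]
    hits[nz] <- hits[nz] + 1
  }
  freq <- hits / n_iter
  out <- tibble(gene = names(freq), frequency = unname(freq),
                selected = unname(freq > freq_min))
  out <- dplyr::arrange(out, dplyr::desc(.data$frequency))
  attr(out, "selected") <- out$gene[out$selected]
  attr(out, "params") <- list(n_iter = n_iter, freq_min = freq_min,
                              subsample_frac = subsample_frac,
                              mixing = mixing, nfolds = nfolds,
                              penalty = penalty, seed = seed,
                              n_redraws = n_redraws)
  out
}

#' Fit the final multivariate Cox signature
#'
#' Unpenalized Cox partial-likelihood fit (Efron tie handling) of survival
#' on the selected genes, each standardized to mean 0 / SD 1 on the training
#' cohort. The fitted object stores the coefficients, the per-gene
#' standardization parameters, and the training-cohort median risk score.
#'
#' @param expr Gene x sample expression matrix (log scale).
#' @param surv Survival tibble with `sample_id`, `time`, `event`.
#' @param genes Genes to include (>= 1, none constant).
#' @param frequencies Optional selection-frequency tibble from
#'   [stability_select()], carried along for reporting.
#' @return An object of class `evosig_model`.
#' @export
fit_cox_signature <- function(expr, surv, genes, frequencies = NULL) {
  m <- as_expr_matrix(expr)
  genes <- as.character(genes)
  if (length(genes) < 1) abort("Need at least one gene.")
  if (!all(genes %in% rownames(m))) {
    abort(sprintf("Genes not in `expr`: %s",
                  paste(setdiff(genes, rownames(m)), collapse = ", ")))
  }
  surv <- surv[match(colnames(m), surv$sample_id), , drop = FALSE]
  if (anyNA(surv$time)) abort("`surv` must cover every expression sample.")
  if (sum(surv$event) <= length(genes)) {
    abort("Need more events than genes for a stable fit.")
  }

  sub <- m[genes, , drop = FALSE]
  center <- rowMeans(sub)
  scale <- row_sds(sub)
  const <- genes[scale == 0 | is.na(scale)]
  if (length(const) > 0) {
    abort(sprintf("Constant gene(s) cannot enter the model: %s",
                  paste(const, collapse = ", ")))
  }
  z <- (sub - center) / scale
  df <- as.data.frame(t(z))
  names(df) <- genes
  df$time <- surv$time
  df$event <- surv$event
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", genes), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w))) {
        abort(paste("Cox fit failed to converge:", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    })
  beta <- stats::setNames(unname(stats::coef(fit)), genes)
  train_scores <- drop(crossprod(z, beta))
  structure(
    list(genes = genes, beta = beta,
         center = stats::setNames(unname(center), genes),
         scale = stats::setNames(unname(scale), genes),
         train_median_score = stats::median(train_scores),
         selection_frequencies = frequencies,
         fit = fit, n = ncol(m), n_events = sum(surv$event)),
    class = "evosig_model")
}

#' @export
print.evosig_model <- function(x, ...) {
  cat("<evosig_model> ", length(x$genes), " genes; ", x$n, " samples, ",
      x$n_events, " events\n", sep = "")
  print(round(x$beta, 3))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-gene coefficients of a fitted signature
#'
#' @param x An `evosig_model`.
#' @param conf.level Confidence level for the hazard-ratio interval.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log hazard per SD), `std.error`,
#'   `statistic`, `p.value`, `hr`, `conf.low`, `conf.high`.
#' @method tidy evosig_model
#' @export
tidy.evosig_model <- function(x, conf.level = 0.95, ...) {
  s <- summary(x$fit, conf.int = conf.level)
  co <- s$coefficients
  ci <- s$conf.int
  tibble(
    term = x$genes,
    estimate = unname(co[, "coef"]),
    std.error = unname(co[, "se(coef)"]),
    statistic = unname(co[, "z"]),
    p.value = unname(co[, "Pr(>|z|)"]),
    hr = unname(ci[, 1]),
    conf.low = unname(ci[, 3]),
    conf.high = unname(ci[, 4])
  )
}

#' One-row model summary of a fitted signature
#'
#' @param x An `evosig_model`.
#' @param ... Unused.
#' @return Tibble: `n`, `n_events`, `n_genes`, `concordance`,
#'   `logLik`, `p.value.lrt`, `train_median_score`.
#' @method glance evosig_model
#' @export
glance.evosig_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n, n_events = x$n_events, n_genes = length(x$genes),
    concordance = unname(s$concordance[1]),
    logLik = unname(stats::logLik(x$fit)[1]),
    p.value.lrt = unname(s$logtest["pvalue"]),
    train_median_score = x$train_median_score
  )
}

#' Risk scores for a cohort under a fitted signature
#'
#' `score_i = sum_g beta_g * z[g, i]`, where z is the per-gene standardized
#' expression: standardized with the training parameters (`"train"`) or
#' re-standardized within the scored cohort (`"cohort"`, the cross-platform
#' default, which makes the score ordering invariant to gene-wise affine
#' rescaling of the input).
#'
#' @param model An `evosig_model`.
#' @param expr Gene x sample matrix containing all model genes.
#' @param standardize `"cohort"` (default) or `"train"`.
#' @param on_missing `"error"` (default) or `"drop"`: drop missing model
#'   genes with a warning instead of failing.
#' @return Tibble: `sample_id`, `score`.
#' @export
score_samples <- function(model, expr,
                          standardize = c("cohort", "train"),
                          on_missing = c("error", "drop")) {
  standardize <- match.arg(standardize)
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(model, "evosig_model"))
  m <- as_expr_matrix(expr)
  genes <- model$genes
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    if (on_missing == "error") {
      abort(sprintf("Model genes missing from `expr`: %s",
                    paste(missing, collapse = ", ")))
    }
    warn(sprintf("Dropping %d model gene(s) absent from `expr`: %s",
                 length(missing), paste(missing, collapse = ", ")))
    genes <- setdiff(genes, missing)
    if (length(genes) == 0) abort("No model genes left to score.")
  }
  sub <- m[genes, , drop = FALSE]
  if (standardize == "train") {
    z <- (sub - model$center[genes]) / model$scale[genes]
  } else {
    ctr <- rowMeans(sub)
    scl <- row_sds(sub)
    scl[scl == 0 | is.na(scl)] <- 1
    z <- (sub - ctr) / scl
  }
  tibble(sample_id = colnames(m),
         score = unname(drop(crossprod(z, model$beta[genes]))))
}

#' Dichotomize risk scores at the cohort median
#'
#' Samples strictly above the cohort median score are labelled high risk;
#' samples at or below the median (including ties at the median) are low
#' risk, a deterministic rule that is conservative toward the high-risk
#' label.
#'
#' @param scores Tibble with `sample_id` and `score` (>= 2 rows).
#' @return The input with a `group` factor column (levels low, high) and
#'   the median in attribute `median_score`.
#' @export
dichotomize <- function(scores) {
  if (!all(c("sample_id", "score") %in% names(scores))) {
    abort("`scores` must have columns sample_id and score.")
  }
  if (nrow(scores) < 2) abort("Need at least 2 samples.")
  med <- stats::median(scores$score)
  out <- dplyr::mutate(scores,
                       group = factor(ifelse(.data$score > med, "high", "low"),
                                      levels = c("low", "high")))
  attr(out, "median_score") <- med
  out
}
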