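#' Run the full signature pipeline on a synthetic study with known truth
#'
#' Generates a complete synthetic study — two multi-region cohorts, a paired
#' tumor-normal set, a survival training cohort and an independent survival
#' test cohort — with a handful of planted evolution-related prognostic
#' genes, then runs every stage of the pipeline: heterogeneity scoring and
#' quadrant classification per multi-region cohort, consensus of the
#' both-high quadrants, paired differential expression, univariate Cox
#' screening, three-way candidate intersection, stability selection,
#' the final multivariate Cox fit, risk scoring and median dichotomization,
#' and survival evaluation (high-vs-low hazard ratio, log-rank p, Harrell's
#' C, IPCW AUC at the median follow-up time).
#'
#' The planted genes are simultaneously high-heterogeneity (Q1 class),
#' differentially expressed, and hazard-linked, so they should survive every
#' filter; `recovery` is the fraction of planted genes in the selected set.
#'
#' @param seed Master seed; every generator call derives its seed from it.
#' @param n_genes Genome size (default 250).
#' @param n_signal Planted signature genes (default 5).
#' @param n_de Genes with a tumor-normal shift, including the signal genes
#'   (default 15).
#' @param n_mr_patients Patients per multi-region cohort (default 30).
#' @param n_pairs Tumor-normal pairs (default 60).
#' @param n_train,n_test Survival cohort sizes (defaults 500 / 300).
#' @param n_iter Stability-selection iterations (default 100).
#' @param freq_min Stability-selection frequency cutoff (default 0.85).
#' @return List with the planted truth, each stage's gene sets, the fitted
#'   `evosig_model`, and a `metrics`-style set of fields: `recovery`,
#'   `high_risk_hr`, `logrank_p`, `c_index`, `auc`, and their `test_*`
#'   counterparts on the held-out cohort.
#' @export
run_synthetic_study <- function(seed = 1, n_genes = 250, n_signal = 5,
                                n_de = 15, n_mr_patients = 30, n_pairs = 60,
                                n_train = 500, n_test = 300, n_iter = 100,
                                freq_min = 0.85) {
  truth <- sim_truth(
    n_genes = n_genes,
    n_prognostic = n_signal,
    beta = rep_len(c(0.9, -0.8, 1.0, -0.9, 0.8), n_signal),
    n_de = n_de, delta = 2,
    seed = seed)
  planted <- truth$genes$gene[truth$genes$beta != 0]

  # stage 1: heterogeneity quadrants per multi-region cohort, then consensus
  quadrant_tables <- lapply(1:2, function(k) {
    mr <- gen_multiregion(truth, n_mr_patients, c(3, 5), seed = seed + k)
    classify_quadrants(heterogeneity_scores(mr$expr, mr$meta))
  })
  evo <- consensus_evogenes(quadrant_tables)

  # stage 2: paired tumor-normal differential expression
  pr <- gen_paired_tumor_normal(truth, n_pairs, seed = seed + 3)
  de_tab <- paired_bulk_de(pr$tumor, pr$normal)
  de <- de_tab$gene[de_tab$significant]

  # stage 3: univariate Cox screen on the training cohort
  train <- gen_survival_cohort(truth, n_train, seed = seed + 4)
  screen <- cox_screen(train$expr, train$surv)
  surv_genes <- screen$gene[screen$significant]

  # stage 4: candidate intersection and stability selection
  candidates <- candidate_genes(evo, de, surv_genes)
  freqs <- stability_select(train$expr, train$surv, candidates,
                            n_iter = n_iter, freq_min = freq_min,
                            seed = seed + 5)
  selected <- attr(freqs, "selected")
  recovery <- mean(planted %in% selected)

  # stage 5: final model, risk scores, dichotomization, evaluation
  model <- fit_cox_signature(train$expr, train$surv, selected,
                             frequencies = freqs)
  evaluate <- function(cohort) {
    scores <- score_samples(model, cohort$expr)
    prof <- dichotomize(scores)
    d <- dplyr::inner_join(prof, cohort$surv, by = "sample_id")
    hr_fit <- cox_fit(data.frame(time = d$time, event = d$event,
                                 high = as.integer(d$group == "high")),
                      "high")
    horizon <- stats::median(d$time)
    list(hr = hr_fit$hr, log_hr_se = hr_fit$std.error,
         logrank_p = logrank_test(d$time, d$event, d$group)$p,
         c_index = harrell_c(d$score, d$time, d$event),
         auc = time_dependent_auc(d$score, d$time, d$event, horizon)$auc,
         horizon = horizon)
  }
  ev_train <- evaluate(train)
  test <- gen_survival_cohort(truth, n_test, seed = seed + 6)
  ev_test <- evaluate(test)

  list(truth = truth, planted = planted, evo = evo, de = de,
       surv_genes = surv_genes, candidates = candidates,
       frequencies = freqs, selected = selected, recovery = recovery,
       model = model,
       high_risk_hr = ev_train$hr, log_hr_se = ev_train$log_hr_se,
       logrank_p = ev_train$logrank_p,
       c_index = ev_train$c_index, auc = ev_train$auc,
       horizon = ev_train$horizon,
       test_high_risk_hr = ev_test$hr, test_log_hr_se = ev_test$log_hr_se,
       test_logrank_p = ev_test$logrank_p,
       test_c_index = ev_test$c_index, test_auc = ev_test$auc)
}
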