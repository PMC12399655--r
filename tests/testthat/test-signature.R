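test_that("candidate set is the exact three-way intersection", {
  expect_identical(candidate_genes(c("a", "b", "c"), c("b", "c", "d"),
                                   c("c", "d", "e")), "c")
  expect_identical(candidate_genes(character(0), c("a"), c("a")),
                   character(0))
  set.seed(50)
  u <- paste0("g", 1:200)
  a <- sample(u, 80); b <- sample(u, 100); c <- sample(u, 120)
  brute <- u[u %in% a & u %in% b & u %in% c]
  expect_setequal(candidate_genes(a, b, c), brute)
})

test_that("stability selection separates a strong signal from noise", {
  t <- sim_truth(n_genes = 40, n_prognostic = 1, beta = 1.5, seed = 51)
  sv <- gen_survival_cohort(t, 250, seed = 52)
  res <- stability_select(sv$expr, sv$surv, rownames(sv$expr),
                          n_iter = 30, seed = 53)
  planted <- t$genes$gene[t$genes$beta != 0]
  expect_gte(res$frequency[res$gene == planted], 0.9)
  noise_freq <- res$frequency[res$gene != planted]
  expect_gte(mean(noise_freq < 0.5), 0.9)
  # reproducible given the master seed
  res2 <- stability_select(sv$expr, sv$surv, rownames(sv$expr),
                           n_iter = 30, seed = 53)
  expect_equal(res$frequency, res2$frequency)
})

test_that("raising the frequency cutoff never adds genes", {
  t <- sim_truth(n_genes = 20, n_prognostic = 2, beta = 1, seed = 54)
  sv <- gen_survival_cohort(t, 200, seed = 55)
  res <- stability_select(sv$expr, sv$surv, rownames(sv$expr),
                          n_iter = 20, freq_min = 0.5, seed = 56)
  sel_low <- res$gene[res$frequency > 0.5]
  sel_high <- res$gene[res$frequency > 0.9]
  expect_true(all(sel_high %in% sel_low))
})

test_that("the final Cox fit recovers planted per-SD log-hazards", {
  t <- sim_truth(n_genes = 30, n_prognostic = 3, beta = c(0.8, -0.6, 0.5),
                 seed = 57)
  sv <- gen_survival_cohort(t, 2000, seed = 58)
  planted <- t$genes$gene[t$genes$beta != 0]
  model <- fit_cox_signature(sv$expr, sv$surv, planted)
  truth_beta <- t$genes$beta[match(planted, t$genes$gene)]
  expect_true(all(abs(model$beta - truth_beta) < 0.15))

  td <- generics::tidy(model)
  expect_identical(td$term, planted)
  expect_equal(td$estimate, unname(model$beta))
  expect_true(all(td$p.value[abs(truth_beta) > 0.4] < 0.01))
  gl <- generics::glance(model)
  expect_equal(gl$n_genes, 3)
  expect_gt(gl$concordance, 0.5)
})

test_that("a binary covariate's coefficient matches the exponential closed form", {
  set.seed(59)
  n <- 4000
  x <- rep(0:1, each = n / 2)
  beta_true <- 0.9
  times <- rexp(n, rate = 0.2 * exp(beta_true * x))
  fit <- cox_fit(data.frame(time = times, event = 1, x = x), "x")
  # beta-hat estimates the log ratio of group event rates
  expect_lt(abs(fit$estimate - beta_true), 0.1)
})

test_that("constant genes and gene mismatches are refused", {
  t <- sim_truth(n_genes = 10, seed = 60)
  sv <- gen_survival_cohort(t, 100, seed = 61)
  expr <- sv$expr
  expr["g0003", ] <- 5
  expect_error(fit_cox_signature(expr, sv$surv, c("g0001", "g0003")),
               "g0003")
  model <- fit_cox_signature(sv$expr, sv$surv, c("g0001", "g0002"))
  expect_error(score_samples(model, sv$expr[-1, , drop = FALSE]), "g0001")
  expect_warning(
    sc <- score_samples(model, sv$expr[-1, , drop = FALSE],
                        on_missing = "drop"),
    "g0001")
  expect_equal(nrow(sc), 100)
})

test_that("risk scores are the stated linear combination", {
  model <- structure(
    list(genes = c("gA", "gB"), beta = c(gA = 0.5, gB = -1),
         center = c(gA = 0, gB = 0), scale = c(gA = 1, gB = 1),
         train_median_score = 0, fit = NULL, n = 2, n_events = 2),
    class = "evosig_model")
  expr <- matrix(c(2, 1), nrow = 2, dimnames = list(c("gA", "gB"), "s1"))
  expect_equal(score_samples(model, expr, standardize = "train")$score, 0)

  # a null model scores everyone zero
  null_model <- model
  null_model$beta[] <- 0
  expr2 <- matrix(rnorm(20), 2, dimnames = list(c("gA", "gB"), paste0("s", 1:10)))
  expect_true(all(score_samples(null_model, expr2, "train")$score == 0))

  # train-mode linearity: shifting one gene by c moves scores by beta*c/SD
  t <- sim_truth(n_genes = 6, seed = 62)
  sv <- gen_survival_cohort(t, 150, seed = 63)
  m <- fit_cox_signature(sv$expr, sv$surv, c("g0001", "g0002"))
  base <- score_samples(m, sv$expr, "train")$score
  shifted_expr <- sv$expr
  shifted_expr["g0002", ] <- shifted_expr["g0002", ] + 3
  shifted <- score_samples(m, shifted_expr, "train")$score
  expect_equal(shifted - base,
               rep(m$beta["g0002"] * 3 / m$scale["g0002"], 150),
               ignore_attr = TRUE)

  # cohort-mode ordering is invariant to gene-wise affine transforms
  affine <- sv$expr * 1.7 + 4
  expect_equal(order(score_samples(m, sv$expr, "cohort")$score),
               order(score_samples(m, affine, "cohort")$score))
})

test_that("median dichotomization applies the tie-to-low rule", {
  s4 <- tibble::tibble(sample_id = paste0("s", 1:4), score = c(1, 2, 3, 4))
  d4 <- dichotomize(s4)
  expect_identical(as.character(d4$group), c("low", "low", "high", "high"))
  s3 <- tibble::tibble(sample_id = paste0("s", 1:3), score = c(1, 2, 3))
  d3 <- dichotomize(s3)
  expect_identical(as.character(d3$group), c("low", "low", "high"))
  # group imbalance is bounded by the number of median ties
  set.seed(64)
  sc <- tibble::tibble(sample_id = paste0("s", 1:101),
                       score = sample(rep(1:20, length.out = 101)))
  d <- dichotomize(sc)
  n_ties <- sum(sc$score == median(sc$score))
  expect_lte(abs(sum(d$group == "high") - sum(d$group == "low")), n_ties)
})

test_that("signature JSON serialization round-trips scoring", {
  t <- sim_truth(n_genes = 8, seed = 65)
  sv <- gen_survival_cohort(t, 120, seed = 66)
  m <- fit_cox_signature(sv$expr, sv$surv, c("g0001", "g0002", "g0003"))
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_json(m, path)
  m2 <- read_signature_json(path)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$center, m$center)
  expect_equal(m2$train_median_score, m$train_median_score)
  expect_equal(score_samples(m2, sv$expr, "train")$score,
               score_samples(m, sv$expr, "train")$score)
})
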