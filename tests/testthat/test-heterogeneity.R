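make_meta <- function(expr, patients) {
  tibble::tibble(sample_id = colnames(expr), patient_id = patients)
}

test_that("heterogeneity scores match hand-computed spread decompositions", {
  # two patients, two regions each
  expr <- rbind(
    g_hand = c(0, 2, 4, 6),     # per-patient SDs sqrt(2); means 1 and 5
    g_const = c(3, 3, 3, 3),    # no variation anywhere
    g_between = c(1, 1, 5, 5)   # identical regions, different patients
  )
  colnames(expr) <- paste0("s", 1:4)
  meta <- make_meta(expr, c("P1", "P1", "P2", "P2"))
  sc <- heterogeneity_scores(expr, meta)
  expect_equal(sc$intra_score[sc$gene == "g_hand"], sqrt(2))
  expect_equal(sc$inter_score[sc$gene == "g_hand"], 2 * sqrt(2))
  expect_equal(sc$intra_score[sc$gene == "g_const"], 0)
  expect_equal(sc$inter_score[sc$gene == "g_const"], 0)
  expect_equal(sc$intra_score[sc$gene == "g_between"], 0)
  expect_gt(sc$inter_score[sc$gene == "g_between"], 0)
})

test_that("patients below min_regions are dropped from the intra median", {
  expr <- rbind(g = c(0, 2, 4, 6, 100))
  colnames(expr) <- paste0("s", 1:5)
  meta <- make_meta(expr, c("P1", "P1", "P2", "P2", "P3"))
  sc <- heterogeneity_scores(expr, meta, min_regions = 2)
  expect_equal(sc$intra_score, sqrt(2))  # P3's singleton cannot contribute
  # but P3 still enters the inter score through its mean
  expect_equal(sc$inter_score, sd(c(1, 5, 100)))
  # fewer than 2 qualifying patients is refused
  meta2 <- make_meta(expr, c("P1", "P1", "P2", "P3", "P4"))
  expect_error(heterogeneity_scores(expr, meta2), ">= 2 patients")
})

test_that("scores are shift-invariant and scale-equivariant", {
  t <- sim_truth(n_genes = 30, seed = 20)
  mr <- gen_multiregion(t, 8, c(3, 5), seed = 21)
  base <- heterogeneity_scores(mr$expr, mr$meta)
  shifted <- mr$expr
  shifted[3, ] <- shifted[3, ] + 7
  sc_shift <- heterogeneity_scores(shifted, mr$meta)
  expect_equal(sc_shift$intra_score, base$intra_score)
  expect_equal(sc_shift$inter_score, base$inter_score)
  scaled <- mr$expr * 2.5
  sc_scale <- heterogeneity_scores(scaled, mr$meta)
  expect_equal(sc_scale$intra_score, base$intra_score * 2.5)
  expect_equal(sc_scale$inter_score, base$inter_score * 2.5)
})

test_that("quadrant labels follow the strict 75th-percentile rule", {
  # 8 hand-set score pairs, checked against a brute-force classifier
  scores <- tibble::tibble(
    gene = paste0("g", 1:8),
    intra_score = c(0.1, 0.2, 0.9, 1.5, 0.3, 2.0, 0.05, 1.1),
    inter_score = c(0.2, 1.8, 0.1, 2.2, 0.4, 0.3, 1.9, 2.0)
  )
  q <- classify_quadrants(scores)
  expect_identical(as.character(q$quadrant),
                   oracle_quadrants(scores$intra_score, scores$inter_score))
  # quadrants partition the genes
  expect_equal(sum(table(q$quadrant)), 8)

  # degenerate ties: identical scores exceed no strict threshold
  flat <- tibble::tibble(gene = paste0("g", 1:6),
                         intra_score = rep(1, 6), inter_score = rep(1, 6))
  qf <- classify_quadrants(flat)
  expect_true(all(qf$quadrant == "Q3"))
  expect_error(classify_quadrants(scores, q = 1.2), "between 0 and 1")
})

test_that("planted both-high genes are recovered as Q1 on simulated cohorts", {
  t <- sim_truth(n_genes = 400, seed = 22)
  mr <- gen_multiregion(t, 50, c(5, 5), seed = 23)
  q <- classify_quadrants(heterogeneity_scores(mr$expr, mr$meta))
  planted <- t$genes$gene[t$genes$class == "Q1"]
  called_q1 <- q$gene[q$quadrant == "Q1"]
  expect_gte(mean(planted %in% called_q1), 0.90)
  # the quadrant size is bounded by the quantile construction
  expect_lte(length(called_q1), ceiling(0.25 * 400))
})

test_that("consensus is the intersection of Q1 sets and shrinks monotonically", {
  mk <- function(genes, q1) tibble::tibble(
    gene = genes, quadrant = factor(ifelse(genes %in% q1, "Q1", "Q3"),
                                    levels = paste0("Q", 1:4)))
  t1 <- mk(letters[1:6], c("a", "b", "c"))
  t2 <- mk(letters[1:6], c("b", "c", "d"))
  t3 <- mk(letters[1:6], c("c", "d", "e"))
  expect_identical(consensus_evogenes(list(t1)), c("a", "b", "c"))
  expect_identical(consensus_evogenes(list(t1, t1)), c("a", "b", "c"))
  expect_identical(consensus_evogenes(list(t1, t2, t3)), "c")
  expect_identical(consensus_evogenes(list(t1, mk(letters[1:6], character(0)))),
                   character(0))
  # adding a table never enlarges the consensus
  expect_true(all(consensus_evogenes(list(t1, t2, t3)) %in%
                    consensus_evogenes(list(t1, t2))))
  expect_error(consensus_evogenes(list()), "non-empty")
})

test_that("enrichment odds ratio matches hand arithmetic", {
  expect_equal(enrichment_odds_ratio(2, 10, 10, 100)$odds_ratio,
               (2 / 8) / (10 / 90))
  expect_equal(enrichment_odds_ratio(5, 50, 20, 200)$odds_ratio, 1)
  zero <- enrichment_odds_ratio(0, 10, 5, 100)
  expect_true(zero$continuity)
  expect_true(is.finite(zero$odds_ratio))
})

test_that("prognostic enrichment detects planted hazard effects and not null sets", {
  t <- sim_truth(n_genes = 150, n_prognostic = 12, beta = 0.7, seed = 24)
  sv <- gen_survival_cohort(t, 500, seed = 25)
  screen <- cox_screen(sv$expr, sv$surv)
  planted <- t$genes$gene[t$genes$beta != 0]
  res <- prognostic_enrichment(planted, screen)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$shift_p, 0.05)

  # random sets stay null in most seeds
  nonsig <- sapply(1:10, function(s) {
    set.seed(s)
    rand <- sample(screen$gene, 15)
    prognostic_enrichment(rand, screen)$shift_p > 0.05
  })
  expect_gte(mean(nonsig), 0.8)
})
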