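#' Per-gene intra- and inter-tumoral heterogeneity scores
#'
#' For each gene, the intra-tumoral score is the median over patients of the
#' sample SD of the gene across that patient's regions (patients with fewer
#' than `min_regions` regions are excluded from this median); the
#' inter-tumoral score is the sample SD across patients of the per-patient
#' mean. Both are in the units of the input expression (log2 by convention).
#' The median-of-SDs form is robust to a single outlier patient; the
#' per-patient summary is pluggable through `method`.
#'
#' @param expr Gene x sample expression matrix (log scale), or a data frame
#'   with a gene column.
#' @param meta Sample metadata with columns `sample_id` and `patient_id`
#'   covering every column of `expr`.
#' @param min_regions Minimum regions a patient needs to contribute to the
#'   intra score (default 2, the smallest for which an SD exists).
#' @param method How per-patient region SDs are pooled into the intra score:
#'   `"median_sd"` (default), `"mean_sd"`, or `"mad"` (median absolute
#'   deviation about the patient median in place of the SD).
#' @return Tibble with one row per gene: `gene`, `intra_score`,
#'   `inter_score`.
#' @export
heterogeneity_scores <- function(expr, meta, min_regions = 2,
                                 method = c("median_sd", "mean_sd", "mad")) {
  method <- match.arg(method)
  m <- as_expr_matrix(expr)
  min_regions <- check_count(min_regions, 2, "min_regions")
  if (!all(c("sample_id", "patient_id") %in% names(meta))) {
    abort("`meta` must have columns sample_id and patient_id.")
  }
  if (anyDuplicated(meta$sample_id)) abort("Duplicate sample ids in `meta`.")
  missing <- setdiff(colnames(m), meta$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("Samples missing from `meta`: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (any(!is.finite(m))) abort("Expression values must all be finite.")

  patient <- meta$patient_id[match(colnames(m), meta$sample_id)]
  split_cols <- split(seq_len(ncol(m)), patient)
  qualifying <- names(split_cols)[lengths(split_cols) >= min_regions]
  if (length(qualifying) < 2) {
    abort(sprintf(
      "Need >= 2 patients with >= %d regions; found %d (patients: %s).",
      min_regions, length(qualifying),
      paste(utils::head(qualifying, 5), collapse = ", ")))
  }

  per_patient_spread <- vapply(qualifying, function(p) {
    sub <- m[, split_cols[[p]], drop = FALSE]
    if (method == "mad") {
      apply(sub, 1, stats::mad)
    } else {
      row_sds(sub)
    }
  }, numeric(nrow(m)))
  per_patient_spread <- matrix(per_patient_spread, nrow = nrow(m))
  intra <- if (method == "mean_sd") {
    rowMeans(per_patient_spread)
  } else {
    apply(per_patient_spread, 1, stats::median)
  }

  patient_means <- vapply(split_cols, function(cols) row_means_of(m, cols),
                          numeric(nrow(m)))
  inter <- row_sds(matrix(patient_means, nrow = nrow(m)))

  tibble(gene = rownames(m), intra_score = unname(intra),
         inter_score = unname(inter))
}

#' Classify genes into heterogeneity quadrants
#'
#' Thresholds each score axis at its `q`-th quantile over all scored genes
#' (linear-interpolation quantile) and labels: Q1 = both scores strictly
#' above threshold, Q2 = inter only, Q4 = intra only, Q3 = neither. Ties at
#' the threshold count as low, so a degenerate axis yields no high genes.
#'
#' @param scores Tibble from [heterogeneity_scores()].
#' @param q Quantile for the high/low cut, in (0, 1); default 0.75.
#' @return The input tibble with a `quadrant` column (factor Q1..Q4) and the
#'   thresholds stored in attribute `thresholds`.
#' @export
classify_quadrants <- function(scores, q = 0.75) {
  if (!all(c("gene", "intra_score", "inter_score") %in% names(scores))) {
    abort("`scores` must come from heterogeneity_scores().")
  }
  if (nrow(scores) < 4) abort("Need scores for at least 4 genes.")
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort("`q` must lie strictly between 0 and 1.")
  }
  thr_intra <- stats::quantile(scores$intra_score, q, type = 7, names = FALSE)
  thr_inter <- stats::quantile(scores$inter_score, q, type = 7, names = FALSE)
  hi_intra <- scores$intra_score > thr_intra
  hi_inter <- scores$inter_score > thr_inter
  quadrant <- dplyr::case_when(
    hi_intra & hi_inter ~ "Q1",
    hi_inter ~ "Q2",
    hi_intra ~ "Q4",
    TRUE ~ "Q3"
  )
  out <- dplyr::mutate(scores,
                       quadrant = factor(quadrant, levels = paste0("Q", 1:4)))
  attr(out, "thresholds") <- c(intra = thr_intra, inter = thr_inter)
  attr(out, "quantile") <- q
  attr(out, "quantile_rule") <- "type 7 (linear interpolation); ties at the threshold are low"
  out
}

#' Consensus evolution-related gene set across cohorts
#'
#' Intersects the Q1 (both-high heterogeneity) gene sets of several
#' per-cohort quadrant tables. Adding a cohort can only shrink the result.
#'
#' @param quadrant_tables List of tibbles from [classify_quadrants()] (or
#'   character vectors of Q1 genes).
#' @return Character vector of consensus genes.
#' @export
consensus_evogenes <- function(quadrant_tables) {
  if (!is.list(quadrant_tables) || length(quadrant_tables) == 0) {
    abort("`quadrant_tables` must be a non-empty list.")
  }
  q1_sets <- lapply(quadrant_tables, function(tab) {
    if (is.character(tab)) return(tab)
    if (!all(c("gene", "quadrant") %in% names(tab))) {
      abort("Each table must have `gene` and `quadrant` columns.")
    }
    tab$gene[tab$quadrant == "Q1"]
  })
  Reduce(intersect, q1_sets)
}

#' Sample odds ratio for gene-set enrichment with an exact test
#'
#' Compares the proportion of hits in a foreground set (`k_in` of `n_in`)
#' against a background proportion (`k_bg` of `n_bg`). The background is the
#' full expressed-gene universe and may contain the foreground; the sample
#' odds ratio is `(k_in/(n_in-k_in)) / (k_bg/(n_bg-k_bg))`, reported with a
#' two-sided Fisher exact p on the 2x2 table. Any zero margin cell triggers
#' a 0.5 continuity correction on the odds ratio, flagged in the output.
#'
#' @param k_in,n_in Hits and size of the foreground set.
#' @param k_bg,n_bg Hits and size of the background universe.
#' @return One-row tibble: `odds_ratio`, `p`, `pct_in`, `pct_bg`,
#'   `continuity` flag.
#' @export
enrichment_odds_ratio <- function(k_in, n_in, k_bg, n_bg) {
  if (k_in < 0 || k_in > n_in || k_bg < 0 || k_bg > n_bg) {
    abort("Counts must satisfy 0 <= k <= n in both groups.")
  }
  cells <- c(k_in, n_in - k_in, k_bg, n_bg - k_bg)
  continuity <- any(cells == 0)
  if (continuity) cells <- cells + 0.5
  or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  p <- stats::fisher.test(matrix(round(c(k_in, n_in - k_in,
                                         k_bg, n_bg - k_bg)), nrow = 2,
                                 byrow = TRUE),
                          alternative = "two.sided")$p.value
  tibble(odds_ratio = or, p = p,
         pct_in = 100 * k_in / n_in, pct_bg = 100 * k_bg / n_bg,
         continuity = continuity)
}

#' Prognostic enrichment of a gene set against a Cox screen
#'
#' Given per-gene univariate Cox p-values, tests whether the set's p-values
#' are shifted relative to the remaining genes (two-sided Wilcoxon rank-sum)
#' and reports the odds ratio for the proportion of prognosis-associated
#' genes (p < `alpha`) in set versus out of set, with a Fisher exact p.
#'
#' @param gene_set Character vector of genes, a subset of the screen.
#' @param cox_screen Tibble with columns `gene` and `p` (e.g. from
#'   [cox_screen()]).
#' @param alpha Prognosis-association threshold on the screen p-values
#'   (default 0.05).
#' @return One-row tibble: `n_set`, `n_other`, `prop_set`, `prop_other`
#'   (proportions with p < alpha), `odds_ratio`, `or_p` (Fisher),
#'   `shift_p` (rank-sum).
#' @export
prognostic_enrichment <- function(gene_set, cox_screen, alpha = 0.05) {
  if (!all(c("gene", "p") %in% names(cox_screen))) {
    abort("`cox_screen` must have columns `gene` and `p`.")
  }
  if (!all(gene_set %in% cox_screen$gene)) {
    abort("`gene_set` must be a subset of the screened genes.")
  }
  in_set <- cox_screen$gene %in% gene_set
  if (sum(in_set) < 10 || sum(!in_set) < 10) {
    abort("Need at least 10 genes inside and outside the set.")
  }
  p_in <- cox_screen$p[in_set]
  p_out <- cox_screen$p[!in_set]
  shift_p <- stats::wilcox.test(p_in, p_out, alternative = "two.sided")$p.value
  k_in <- sum(p_in < alpha, na.rm = TRUE)
  k_out <- sum(p_out < alpha, na.rm = TRUE)
  tab <- matrix(c(k_in, length(p_in) - k_in,
                  k_out, length(p_out) - k_out), nrow = 2, byrow = TRUE)
  fish <- stats::fisher.test(tab, alternative = "two.sided")
  cells <- as.numeric(t(tab))
  or <- if (any(cells == 0)) {
    prod(cells[c(1, 4)] + 0.5) / prod(cells[c(2, 3)] + 0.5)
  } else {
    (cells[1] / cells[2]) / (cells[3] / cells[4])
  }
  tibble(n_set = length(p_in), n_other = length(p_out),
         prop_set = k_in / length(p_in), prop_other = k_out / length(p_out),
         odds_ratio = or, or_p = fish$p.value, shift_p = shift_p)
}
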