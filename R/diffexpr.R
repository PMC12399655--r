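#' Paired tumor-normal differential expression on log2 values
#'
#' Per gene, a two-sided paired rank test (Wilcoxon signed-rank; exact for
#' up to `exact_max` pairs, mid-rank normal approximation with tie and
#' continuity correction beyond) on the log2 expression of matched
#' tumor-normal pairs. The effect size is the mean paired log2 difference;
#' p-values are Benjamini-Hochberg adjusted across tested genes. A gene is
#' called significant when `|log2_fc| > lfc_min` (strict) and the adjusted
#' p is below `alpha`. All-constant differences leave the test undefined;
#' such genes are reported with p = 1 and flagged.
#'
#' @param tumor,normal Gene x sample matrices on the log2 scale with
#'   identical gene sets; columns are matched pairs, aligned by position or
#'   via `pairs`.
#' @param pairs Optional tibble with columns `tumor_id`, `normal_id` naming
#'   the matched columns.
#' @param lfc_min Absolute log2 fold-change threshold (default 1.0).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param exact_max Largest pair count for which the exact signed-rank
#'   distribution is used (default 25).
#' @return Tibble: `gene`, `log2_fc`, `p`, `p_adjusted`, `significant`,
#'   `constant`.
#' @export
paired_bulk_de <- function(tumor, normal, pairs = NULL, lfc_min = 1.0,
                           alpha = 0.05, exact_max = 25) {
  tumor <- as_expr_matrix(tumor, "tumor")
  normal <- as_expr_matrix(normal, "normal")
  if (!identical(rownames(tumor), rownames(normal))) {
    abort("`tumor` and `normal` must share an identical gene set and order.")
  }
  if (!is.null(pairs)) {
    if (!all(c("tumor_id", "normal_id") %in% names(pairs))) {
      abort("`pairs` must have columns tumor_id and normal_id.")
    }
    tumor <- tumor[, pairs$tumor_id, drop = FALSE]
    normal <- normal[, pairs$normal_id, drop = FALSE]
  }
  if (ncol(tumor) != ncol(normal)) {
    abort("Tumor and normal inputs are not paired: unequal sample counts.")
  }
  n_pairs <- ncol(tumor)
  if (n_pairs < 3) abort("Need at least 3 pairs.")

  d <- tumor - normal
  log2_fc <- rowMeans(d)
  use_exact <- n_pairs <= exact_max
  p <- apply(d, 1, function(di) {
    if (all(di == 0)) return(NA_real_)
    tryCatch(
      # falls back to the tie-corrected normal approximation when exact
      # signed-rank probabilities are undefined (ties/zeros)
      suppressWarnings(
        stats::wilcox.test(di, exact = use_exact, correct = TRUE)$p.value),
      error = function(e) NA_real_
    )
  })
  constant <- is.na(p)
  p[constant] <- 1
  p_adjusted <- stats::p.adjust(p, method = "BH")
  tibble(
    gene = rownames(tumor),
    log2_fc = unname(log2_fc),
    p = unname(p),
    p_adjusted = unname(p_adjusted),
    significant = abs(log2_fc) > lfc_min & p_adjusted < alpha,
    constant = unname(constant)
  )
}

# Library-size normalization used for all single-cell comparisons:
# counts scaled to a fixed library size then log1p.
normalize_cells <- function(counts, scale_factor = 1e4) {
  libsize <- colSums(counts)
  libsize[libsize == 0] <- 1
  log1p(sweep(counts, 2, libsize / scale_factor, "/"))
}

#' Two-group single-cell differential expression
#'
#' Wilcoxon rank-sum test per gene on log-normalized expression (counts
#' scaled to a common library size of `scale_factor`, then log1p), between
#' two cell groups defined by a metadata column. Genes enter the test only
#' if detected (count > 0) in at least `min_pct` of cells in one of the two
#' groups. The log fold change is the difference of group means of the
#' log-normalized values (group A minus group B). Adjusted p-values use
#' Benjamini-Hochberg by default (Bonferroni by flag); a gene is significant
#' when `|logFC| > lfc_min` and adjusted p < `alpha`. Each group must have
#' at least `min_cells` cells.
#'
#' @param counts Gene x cell count matrix (base or Matrix sparse).
#' @param meta Cell metadata with a `cell_id` column covering the matrix
#'   columns.
#' @param group_by Metadata column defining the comparison.
#' @param a,b Levels of `group_by` to compare (logFC is a minus b).
#' @param cell_type Optional cell-type restriction (uses the `cell_type`
#'   column).
#' @param min_pct Detection fraction required in at least one group
#'   (default 0.10).
#' @param lfc_min Log fold-change magnitude for the significance call
#'   (default 0.25).
#' @param min_cells Minimum cells per group (default 10).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param adjust Multiple-testing method: `"BH"` (default) or
#'   `"bonferroni"`.
#' @param scale_factor Target library size for normalization (default 1e4).
#' @return Tibble: `gene`, `logFC`, `p`, `p_adjusted`, `pct_a`, `pct_b`,
#'   `significant`, for tested genes only.
#' @export
sc_de <- function(counts, meta, group_by, a, b, cell_type = NULL,
                  min_pct = 0.10, lfc_min = 0.25, min_cells = 10,
                  alpha = 0.05, adjust = c("BH", "bonferroni"),
                  scale_factor = 1e4) {
  adjust <- match.arg(adjust)
  counts <- as.matrix(counts)
  if (!"cell_id" %in% names(meta)) abort("`meta` must have a cell_id column.")
  if (!group_by %in% names(meta)) {
    abort(sprintf("Column `%s` not found in `meta`.", group_by))
  }
  meta <- meta[match(colnames(counts), meta$cell_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(cell_type)) keep <- keep & meta$cell_type == cell_type
  cells_a <- which(keep & meta[[group_by]] == a)
  cells_b <- which(keep & meta[[group_by]] == b)
  if (length(cells_a) < min_cells) {
    abort(sprintf("Group '%s' has %d cells; at least %d required.",
                  a, length(cells_a), min_cells))
  }
  if (length(cells_b) < min_cells) {
    abort(sprintf("Group '%s' has %d cells; at least %d required.",
                  b, length(cells_b), min_cells))
  }

  sub <- counts[, c(cells_a, cells_b), drop = FALSE]
  norm <- normalize_cells(sub, scale_factor)
  ia <- seq_along(cells_a)
  ib <- length(cells_a) + seq_along(cells_b)
  pct_a <- rowMeans(sub[, ia, drop = FALSE] > 0)
  pct_b <- rowMeans(sub[, ib, drop = FALSE] > 0)
  tested <- pct_a >= min_pct | pct_b >= min_pct
  if (!any(tested)) {
    return(tibble(gene = character(), logFC = numeric(), p = numeric(),
                  p_adjusted = numeric(), pct_a = numeric(),
                  pct_b = numeric(), significant = logical()))
  }

  norm_t <- norm[tested, , drop = FALSE]
  logFC <- rowMeans(norm_t[, ia, drop = FALSE]) -
    rowMeans(norm_t[, ib, drop = FALSE])
  p <- apply(norm_t, 1, function(v) {
    if (all(v == v[1])) return(1)
    stats::wilcox.test(v[ia], v[ib], exact = FALSE, correct = TRUE)$p.value
  })
  p_adjusted <- stats::p.adjust(p, method = adjust)
  tibble(
    gene = rownames(norm_t),
    logFC = unname(logFC),
    p = unname(p),
    p_adjusted = unname(p_adjusted),
    pct_a = unname(pct_a[tested]),
    pct_b = unname(pct_b[tested]),
    significant = abs(logFC) > lfc_min & p_adjusted < alpha
  )
}
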