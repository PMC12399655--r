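#' Classify sustained regional expression trends across ordered tissue zones
#'
#' Calls each gene sustained-up, sustained-down, or no-trend across the
#' ordered zones non-tumor (N), tumor border (B) and tumor core (T) within
#' one cell type. A gene is "up" when its mean log-normalized expression
#' increases strictly at both steps (N < B < T) and the step comparisons
#' reach single-cell DE significance: relaxed mode requires the endpoint
#' comparison (N vs T) to be significant, strict mode requires both
#' adjacent steps (N vs B and B vs T). "down" is symmetric; everything else
#' is "none". DE significance and the minimum 10 cells per zone are
#' inherited from [sc_de()].
#'
#' @param counts Gene x cell count matrix.
#' @param meta Cell metadata: `cell_id`, `region`, `cell_type`.
#' @param cell_type Cell type to analyze.
#' @param mode `"relaxed"` (default) or `"strict"`.
#' @param zones Ordered zone labels (default c("N", "B", "T")). Reversing
#'   the order swaps up and down calls.
#' @param min_pct,lfc_min,min_cells,alpha,adjust Passed to [sc_de()].
#' @return Tibble: `gene`, `direction`, `d_step1`, `d_step2` (mean
#'   log-normalized differences for the two zone steps), `sig_endpoint`,
#'   `sig_step1`, `sig_step2`, `mode`.
#' @export
classify_regional_trend <- function(counts, meta, cell_type,
                                    mode = c("relaxed", "strict"),
                                    zones = c("N", "B", "T"),
                                    min_pct = 0.10, lfc_min = 0.25,
                                    min_cells = 10, alpha = 0.05,
                                    adjust = "BH") {
  mode <- match.arg(mode)
  if (length(zones) != 3) abort("`zones` must name three ordered zones.")
  counts <- as.matrix(counts)
  meta_ct <- meta[meta$cell_type == cell_type, , drop = FALSE]
  zone_n <- vapply(zones, function(z) sum(meta_ct$region == z), integer(1))
  if (any(zone_n < min_cells)) {
    bad <- zones[zone_n < min_cells]
    abort(sprintf(
      "Cell type '%s' lacks zones with >= %d cells: %s (sizes %s).",
      cell_type, min_cells, paste(bad, collapse = ", "),
      paste(zone_n[zone_n < min_cells], collapse = ", ")))
  }

  norm <- normalize_cells(counts[, meta$cell_id[meta$cell_type == cell_type],
                                 drop = FALSE])
  zone_means <- vapply(zones, function(z) {
    rowMeans(norm[, meta_ct$region == z, drop = FALSE])
  }, numeric(nrow(norm)))
  d1 <- zone_means[, 2] - zone_means[, 1]
  d2 <- zone_means[, 3] - zone_means[, 2]

  de_sig <- function(a, b) {
    de <- sc_de(counts, meta, group_by = "region", a = a, b = b,
                cell_type = cell_type, min_pct = min_pct,
                lfc_min = lfc_min, min_cells = min_cells, alpha = alpha,
                adjust = adjust)
    v <- stats::setNames(rep(FALSE, nrow(norm)), rownames(norm))
    v[de$gene] <- de$significant
    v
  }
  sig_endpoint <- de_sig(zones[3], zones[1])
  if (mode == "strict") {
    sig_s1 <- de_sig(zones[2], zones[1])
    sig_s2 <- de_sig(zones[3], zones[2])
    sig_ok <- sig_s1 & sig_s2
  } else {
    sig_s1 <- rep(NA, nrow(norm))
    sig_s2 <- rep(NA, nrow(norm))
    sig_ok <- sig_endpoint
  }

  direction <- dplyr::case_when(
    d1 > 0 & d2 > 0 & sig_ok ~ "up",
    d1 < 0 & d2 < 0 & sig_ok ~ "down",
    TRUE ~ "none"
  )
  tibble(gene = rownames(norm), direction = direction,
         d_step1 = unname(d1), d_step2 = unname(d2),
         sig_endpoint = unname(sig_endpoint),
         sig_step1 = unname(sig_s1), sig_step2 = unname(sig_s2),
         mode = mode)
}
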