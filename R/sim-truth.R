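#' Ground-truth parameter table for the synthetic study generators
#'
#' Builds the single object all synthetic generators consume: a per-gene
#' parameter table (heterogeneity class, baseline mean, variance components,
#' hazard coefficient, tumor-normal shift, regional mean multipliers) plus
#' the study-level scalars (baseline hazard, censoring horizon, count
#' dispersion, paired-noise SD).
#'
#' Genes are laid out in class blocks (Q1, Q2, Q3, Q4, flat) sized by
#' `class_prop`. Classes encode the two variance axes of multi-region
#' expression: `sigma_intra` is the SD of region-level noise within a
#' patient's tumor, `sigma_inter` the SD of patient-level offsets, both in
#' log2-expression units. Planted effects are assigned to the leading genes
#' of the Q1 block so that prognostic, differential and trend effects nest:
#' the first `min(n_prognostic, n_de)` Q1 genes carry both a hazard
#' coefficient and a tumor-normal shift, mimicking evolution-related genes
#' that survive every filter of the signature pipeline.
#'
#' @param n_genes Number of genes.
#' @param class_prop Named proportions over classes Q1, Q2, Q3, Q4, flat.
#'   Defaults keep both high-variance fractions below 0.25 so that planted
#'   Q1 genes sit above 75th-percentile thresholds.
#' @param sigma_intra,sigma_inter Named per-class SDs (log2 units).
#' @param mu_range Range of baseline log2 means, drawn uniformly.
#' @param n_prognostic Number of genes given a nonzero hazard coefficient.
#' @param beta Per-SD log-hazard for prognostic genes (recycled).
#' @param n_de Number of genes given a nonzero tumor-normal shift.
#' @param delta Log2 shift for differential genes (recycled).
#' @param n_trend_up,n_trend_down Numbers of genes with monotone regional
#'   mean multipliers across ordered zones N, B, T.
#' @param trend_ratio Fold change per zone step for trend genes; up-genes get
#'   multipliers (1, r, r^2), down-genes (1, 1/r, 1/r^2).
#' @param h0 Baseline hazard (events per time unit).
#' @param c_max Censoring horizon: censoring times are Uniform(0, c_max).
#' @param dispersion Shared negative-binomial dispersion for cell counts
#'   (variance = mu + dispersion * mu^2).
#' @param pair_noise_sd Noise SD (log2) for the paired tumor-normal design.
#' @param seed Integer seed; the baseline means are the only random draw.
#'
#' @return An object of class `sim_truth`: list with `genes` (a tibble, one
#'   row per gene) and the scalar parameters.
#' @export
sim_truth <- function(n_genes = 500,
                      class_prop = c(Q1 = 0.10, Q2 = 0.10, Q3 = 0.55,
                                     Q4 = 0.10, flat = 0.15),
                      sigma_intra = c(Q1 = 2, Q2 = 0.3, Q3 = 0.3,
                                      Q4 = 2, flat = 0.1),
                      sigma_inter = c(Q1 = 2, Q2 = 2, Q3 = 0.3,
                                      Q4 = 0.3, flat = 0.1),
                      mu_range = c(4, 12),
                      n_prognostic = 0, beta = 0.8,
                      n_de = 0, delta = 2,
                      n_trend_up = 0, n_trend_down = 0, trend_ratio = 2,
                      h0 = 0.1, c_max = 30, dispersion = 0.5,
                      pair_noise_sd = 0.5, seed = 1) {
  n_genes <- check_count(n_genes, 1, "n_genes")
  classes <- c("Q1", "Q2", "Q3", "Q4", "flat")
  if (!setequal(names(class_prop), classes)) {
    abort("`class_prop` must be named with Q1, Q2, Q3, Q4, flat.")
  }
  if (any(sigma_intra < 0) || any(sigma_inter < 0)) {
    abort("All class SDs must be >= 0.")
  }
  if (h0 <= 0) abort("`h0` must be > 0.")
  if (c_max <= 0) abort("`c_max` must be > 0.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (trend_ratio <= 0) abort("`trend_ratio` must be > 0.")

  counts <- diff(c(0, round(cumsum(class_prop[classes] / sum(class_prop)) * n_genes)))
  gene_class <- rep(classes, counts)

  set.seed(seed)
  mu <- stats::runif(n_genes, mu_range[1], mu_range[2])

  genes <- tibble(
    gene = sprintf("g%04d", seq_len(n_genes)),
    class = gene_class,
    mu = mu,
    sigma_intra = unname(sigma_intra[gene_class]),
    sigma_inter = unname(sigma_inter[gene_class]),
    beta = 0,
    delta = 0,
    m_N = 1, m_B = 1, m_T = 1,
    cell_mean = 2^((mu - 4) / 2)
  )

  q1_idx <- which(genes$class == "Q1")
  if (n_prognostic > 0) {
    if (n_prognostic > length(q1_idx)) {
      abort("More prognostic genes requested than Q1-class genes available.")
    }
    genes$beta[q1_idx[seq_len(n_prognostic)]] <-
      rep_len(beta, n_prognostic)
  }
  if (n_de > 0) {
    if (n_de > length(q1_idx)) {
      abort("More differential genes requested than Q1-class genes available.")
    }
    genes$delta[q1_idx[seq_len(n_de)]] <- rep_len(delta, n_de)
  }
  n_trend <- n_trend_up + n_trend_down
  if (n_trend > 0) {
    if (n_trend > n_genes) abort("More trend genes requested than genes.")
    up_idx <- seq_len(n_trend_up)
    down_idx <- n_trend_up + seq_len(n_trend_down)
    r <- trend_ratio
    if (n_trend_up > 0) {
      genes$m_B[up_idx] <- r
      genes$m_T[up_idx] <- r^2
    }
    if (n_trend_down > 0) {
      genes$m_B[down_idx] <- 1 / r
      genes$m_T[down_idx] <- 1 / r^2
    }
  }
  genes$trend <- dplyr::case_when(
    genes$m_N < genes$m_B & genes$m_B < genes$m_T ~ "up",
    genes$m_N > genes$m_B & genes$m_B > genes$m_T ~ "down",
    TRUE ~ "none"
  )

  structure(
    list(genes = genes, h0 = h0, c_max = c_max, dispersion = dispersion,
         pair_noise_sd = pair_noise_sd, seed = seed),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$genes), " genes; h0 = ", x$h0,
      ", c_max = ", x$c_max, "\n", sep = "")
  print(table(x$genes$class))
  invisible(x)
}
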