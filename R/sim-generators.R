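#' Simulate a multi-region expression cohort
#'
#' Draws log2 expression for every gene in `truth` over a cohort of patients
#' each sampled in several tumor regions:
#' `x[g, p, r] = mu_g + a[g, p] + e[g, p, r]` with patient offsets
#' `a ~ Normal(0, sigma_inter^2)` and region noise
#' `e ~ Normal(0, sigma_intra^2)`, both class-specific. Region counts per
#' patient are drawn uniformly from `regions_range`; the default 3-5 regions
#' matches the sampling depth typical of multi-region tumor studies.
#'
#' @param truth A [sim_truth()] object.
#' @param n_patients Number of patients (>= 2).
#' @param regions_range Integer interval (within 2..10) for per-patient
#'   region counts.
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   dataset bit for bit.
#' @return List of class `sim_multiregion`: `expr` (gene x sample matrix of
#'   log2 values), `meta` (tibble: sample_id, patient_id, region_id), and
#'   the `truth` object.
#' @export
gen_multiregion <- function(truth, n_patients = 37, regions_range = c(3, 5),
                            seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  n_patients <- check_count(n_patients, 2, "n_patients")
  if (length(regions_range) != 2 || any(is.na(regions_range))) {
    abort("`regions_range` must be an interval c(lo, hi).")
  }
  lo <- as.integer(regions_range[1]); hi <- as.integer(regions_range[2])
  if (lo > hi || lo < 2 || hi > 10) {
    abort("`regions_range` must lie within [2, 10] with lo <= hi.")
  }

  g <- truth$genes
  n_genes <- nrow(g)
  set.seed(seed)
  choices <- lo:hi  # guard against sample()'s scalar expansion when lo == hi
  n_regions <- choices[sample.int(length(choices), n_patients, replace = TRUE)]
  patient_ids <- sprintf("P%03d", seq_len(n_patients))
  meta <- tibble(
    patient_id = rep(patient_ids, n_regions),
    region_id = unlist(lapply(n_regions, function(k) sprintf("R%d", seq_len(k))))
  )
  meta$sample_id <- paste(meta$patient_id, meta$region_id, sep = "_")
  meta <- meta[, c("sample_id", "patient_id", "region_id")]

  a <- matrix(stats::rnorm(n_genes * n_patients, 0, g$sigma_inter),
              nrow = n_genes)                       # gene x patient offsets
  e <- matrix(stats::rnorm(n_genes * nrow(meta), 0, g$sigma_intra),
              nrow = n_genes)
  pat_idx <- rep(seq_len(n_patients), n_regions)
  expr <- g$mu + a[, pat_idx, drop = FALSE] + e
  dimnames(expr) <- list(g$gene, meta$sample_id)

  structure(list(expr = expr, meta = meta, truth = truth),
            class = "sim_multiregion")
}

#' Simulate a proportional-hazards survival cohort with linked expression
#'
#' Per-sample expression is `x[g, i] ~ Normal(mu_g, s_g)` with total SD
#' `s_g = sqrt(sigma_intra^2 + sigma_inter^2)` from the gene's class. The
#' hazard is `h_i = h0 * exp(sum_g beta_g * z[g, i])` on the true z-score
#' `z = (x - mu_g) / s_g`; event times are Exponential(h_i), censoring times
#' Uniform(0, c_max), observed time the minimum with an event indicator.
#' Uncorrelated clinical covariates (age, sex, stage) are attached for
#' adjustment exercises; they carry no effect.
#'
#' @param truth A [sim_truth()] object; genes with nonzero `beta` drive the
#'   hazard.
#' @param n Cohort size (>= 10).
#' @param seed Integer seed.
#' @return List of class `sim_survival`: `expr` (gene x sample log2 matrix),
#'   `surv` (tibble: sample_id, time, event, age, sex, stage), `truth`.
#' @export
gen_survival_cohort <- function(truth, n = 500, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  n <- check_count(n, 10, "n")
  g <- truth$genes
  if (nrow(g) == 0) abort("`truth` defines no genes.")

  set.seed(seed)
  n_genes <- nrow(g)
  s <- sqrt(g$sigma_intra^2 + g$sigma_inter^2)
  x <- g$mu + matrix(stats::rnorm(n_genes * n, 0, s), nrow = n_genes)
  sample_ids <- sprintf("S%04d", seq_len(n))
  dimnames(x) <- list(g$gene, sample_ids)

  z <- (x - g$mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  lp <- drop(crossprod(z, g$beta))
  haz <- truth$h0 * exp(lp)
  t_event <- stats::rexp(n, rate = haz)
  t_cens <- stats::runif(n, 0, truth$c_max)
  surv <- tibble(
    sample_id = sample_ids,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    age = round(stats::rnorm(n, 60, 10)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stage = sample(1:4, n, replace = TRUE, prob = c(0.35, 0.3, 0.25, 0.1))
  )

  structure(list(expr = x, surv = surv, truth = truth),
            class = "sim_survival")
}

#' Simulate a paired tumor-normal expression set
#'
#' For each pair, the normal sample is `mu_g + noise` and the tumor sample
#' `mu_g + delta_g + noise`, with independent Normal(0, `pair_noise_sd`)
#' noise on the log2 scale. Genes with `delta_g != 0` in the truth table are
#' the planted differential genes.
#'
#' @param truth A [sim_truth()] object.
#' @param n_pairs Number of subject pairs (>= 3).
#' @param seed Integer seed.
#' @return List of class `sim_paired`: `tumor` and `normal` (gene x pair
#'   matrices, columns aligned by subject), `pairs` (tibble: pair_id,
#'   tumor_id, normal_id), `truth`.
#' @export
gen_paired_tumor_normal <- function(truth, n_pairs = 50, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  n_pairs <- check_count(n_pairs, 3, "n_pairs")
  g <- truth$genes
  set.seed(seed)
  n_genes <- nrow(g)
  sd <- truth$pair_noise_sd
  normal <- g$mu + matrix(stats::rnorm(n_genes * n_pairs, 0, sd), n_genes)
  tumor <- g$mu + g$delta +
    matrix(stats::rnorm(n_genes * n_pairs, 0, sd), n_genes)
  pair_ids <- sprintf("Pair%03d", seq_len(n_pairs))
  dimnames(normal) <- list(g$gene, paste0(pair_ids, "_N"))
  dimnames(tumor) <- list(g$gene, paste0(pair_ids, "_T"))
  pairs <- tibble(pair_id = pair_ids,
                  tumor_id = colnames(tumor),
                  normal_id = colnames(normal))
  structure(list(tumor = tumor, normal = normal, pairs = pairs,
                 truth = truth),
            class = "sim_paired")
}

#' Simulate region-labelled single-cell counts with planted zone gradients
#'
#' Counts for gene g in zone rho are negative binomial with mean
#' `cell_mean_g * m[g, rho]` and shared dispersion, over the ordered zones
#' non-tumor (N), tumor border (B) and tumor core (T). Genes whose
#' multipliers increase monotonically N < B < T are truth-labelled "up",
#' decreasing ones "down", all others "none".
#'
#' @param truth A [sim_truth()] object.
#' @param cells_per_region Cells per zone (>= 10).
#' @param regions Zones to emit, a subset of c("N", "B", "T") in order.
#' @param cell_type Cell-type label attached to every cell.
#' @param seed Integer seed.
#' @return List of class `sim_cells`: `counts` (gene x cell integer matrix),
#'   `meta` (tibble: cell_id, region, cell_type, patient), `truth`.
#' @export
gen_regional_cells <- function(truth, cells_per_region = 200,
                               regions = c("N", "B", "T"),
                               cell_type = "EPI", seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  cells_per_region <- check_count(cells_per_region, 10, "cells_per_region")
  if (!all(regions %in% c("N", "B", "T")) || length(regions) == 0) {
    abort("`regions` must be a non-empty subset of c(\"N\", \"B\", \"T\").")
  }
  g <- truth$genes
  set.seed(seed)
  n_genes <- nrow(g)
  mult <- cbind(N = g$m_N, B = g$m_B, T = g$m_T)
  size <- if (truth$dispersion > 0) 1 / truth$dispersion else Inf
  blocks <- lapply(regions, function(rg) {
    mu <- g$cell_mean * mult[, rg]
    if (is.finite(size)) {
      matrix(stats::rnbinom(n_genes * cells_per_region, mu = mu, size = size),
             nrow = n_genes)
    } else {
      matrix(stats::rpois(n_genes * cells_per_region, lambda = mu),
             nrow = n_genes)
    }
  })
  counts <- do.call(cbind, blocks)
  meta <- tibble(
    region = rep(regions, each = cells_per_region),
    cell_type = cell_type,
    patient = "P001"
  )
  meta$cell_id <- sprintf("%s_c%05d", meta$region,
                          stats::ave(seq_len(nrow(meta)), meta$region,
                                     FUN = seq_along))
  meta <- meta[, c("cell_id", "region", "cell_type", "patient")]
  dimnames(counts) <- list(g$gene, meta$cell_id)
  structure(list(counts = counts, meta = meta, truth = truth),
            class = "sim_cells")
}
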