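---
title: "Methods: evolutionary expression signatures from multi-region tumor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary expression signatures from multi-region tumor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Multi-region sampling of a solid tumor yields several expression profiles
per patient. Writing $x_{g,p,r}$ for the log2 expression of gene $g$ in
region $r$ of patient $p$, the package decomposes a gene's variability into
two axes:

- **intra-tumoral heterogeneity**: variation among regions of one tumor,
  summarized here as the median over patients of the within-patient sample
  SD of $x_{g,p,\cdot}$;
- **inter-tumoral heterogeneity**: variation of tumor-level expression
  between patients, summarized as the sample SD across patients of the
  per-patient mean.

Both scores are in log2-expression SD units. Each axis is cut at its 75th
percentile over all scored genes (linear-interpolation quantile, type 7),
and genes strictly above both thresholds form quadrant Q1 — genes whose
regional variability may track clonal evolution and whose between-patient
variability makes them usable biomarkers. Q2 is inter-only, Q4 intra-only,
Q3 neither. Intersecting Q1 sets across independent multi-region cohorts
gives the consensus evolution-related gene set.

Candidates for the prognostic signature are the three-way intersection of
(i) the consensus set, (ii) genes differentially expressed between paired
tumor and normal tissue (paired rank test on log2 values; significant when
$|\log_2 FC| > 1$ strictly and BH-adjusted $p < 0.05$), and (iii) genes
passing a univariate Cox screen ($p < 0.05$). Stability selection then
subsamples the training cohort (80% without replacement, 1,000 iterations
by default), fits an L1-penalized Cox model per subsample with the penalty
chosen by 5-fold cross-validated partial likelihood, and keeps genes whose
selection frequency exceeds 0.85 — the analogue of "chosen in more than
850 of 1,000 iterations". The final signature is an unpenalized
multivariate Cox fit on the standardized selected genes; the risk score is
the linear predictor

$$ r_i = \sum_g \beta_g z_{g,i}, \qquad z_{g,i} = \frac{x_{g,i} - m_g}{s_g}, $$

and cohorts are dichotomized at their own median score (ties at the median
go to low risk). Evaluation uses Kaplan–Meier curves, the log-rank test,
Harrell's C, and cumulative/dynamic time-dependent AUC with
inverse-probability-of-censoring weights (IPCW) from the Kaplan–Meier
estimate of the censoring distribution.

# Tunable parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| quadrant quantile `q` | 0.75 | per-axis high/low cut |
| `min_regions` | 2 | regions a patient needs to enter the intra score |
| bulk DE `lfc_min`, `alpha` | 1.0, 0.05 | log2 units; BH-adjusted p |
| sc DE `min_pct`, `lfc_min`, `min_cells` | 0.10, 0.25, 10 | detection fraction; log fold change of log1p-normalized means; group floor |
| `n_iter`, `freq_min`, `subsample_frac` | 1000, 0.85, 0.8 | stability selection |
| `mixing` | 1 | elastic-net mixing (1 = lasso) |
| scoring `standardize` | `"cohort"` | per-cohort z-scoring (cross-platform default); `"train"` uses training parameters |
| censoring horizon `c_max` | 30 | time units; Uniform(0, c_max) censoring |
| baseline hazard `h0` | 0.1 | events per time unit |
| NB `dispersion` | 0.5 | shared cell-count overdispersion |

# What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline consumes, with a
ground-truth table so each stage can be tested against known parameters.

- `gen_multiregion()` draws $x_{g,p,r} = \mu_g + a_{g,p} + e_{g,p,r}$ with
  Gaussian patient offsets ($\sigma_\text{inter}$) and region noise
  ($\sigma_\text{intra}$) on the log2 scale, 3–5 regions per patient by
  default — the sampling depth typical of multi-region tumor studies.
  Class SDs default to 2 (high) vs 0.3 (low), well-separated so the
  quadrant classifier's recovery can be measured cleanly.
- `gen_survival_cohort()` uses exponential event times with hazard
  $h_i = h_0 \exp(\sum_g \beta_g z_{g,i})$ and independent
  Uniform$(0, c_\text{max})$ censoring — the simplest proportional-hazards
  model, chosen because it admits closed-form checks
  ($S(t\mid x) = e^{-h_0 t e^{\beta x}}$). The defaults $h_0 = 0.1$,
  $c_\text{max} = 30$ give roughly one-third censoring, a realistic
  clinical fraction. Expression is $N(\mu_g, s_g)$ with
  $s_g = \sqrt{\sigma_\text{intra}^2 + \sigma_\text{inter}^2}$, and the
  hazard acts on the true z-score, so planted $\beta$ are per-SD
  log-hazards.
- `gen_paired_tumor_normal()` plants log2 shifts $\delta_g$ over Gaussian
  noise (SD 0.5).
- `gen_regional_cells()` draws negative-binomial counts with shared
  dispersion 0.5 and zone mean multipliers $(1, r, r^2)$ for planted
  monotone gradients across non-tumor (N), border (B) and core (T) zones;
  count-scale baselines are $2^{(\mu_g - 4)/2}$, mapping the log2 bulk
  means onto realistic per-cell count magnitudes (~1–16).

Deliberately **not** emulated: platform and batch effects, probe
structure, correlated gene modules, dropout beyond NB overdispersion,
non-proportional hazards, informative censoring, and patient-level
confounding in the cell data (one synthetic donor). Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to every artifact of real cohorts.

# Numerical and design choices

- **Heterogeneity metric.** The median-over-patients of within-patient SDs
  is robust to one outlier patient and shares units with the inter score;
  `method = "mean_sd"` and `"mad"` are available behind the same surface,
  so an alternative operationalization can be slotted in.
- **Quadrant ties.** Strict inequality at the quantile threshold; ties are
  "low". Deterministic, and conservative about calling a gene high — a
  degenerate axis (all scores equal) yields no high genes at all. Only Q1
  has an external definition; the Q2/inter-only, Q4/intra-only, Q3/both-low
  labelling is this package's convention and is configurable downstream by
  using the scores directly.
- **Enrichment background.** The background universe includes the
  foreground set (the sample odds ratio is computed on the two raw
  proportions); this matches the worked 28/192-vs-449/12,429 arithmetic
  that yields OR = 4.55.
- **Paired bulk DE** is a paired Wilcoxon signed-rank test on log2 values
  — not a negative-binomial count model — exact for ≤ 25 pairs, tie- and
  continuity-corrected normal approximation beyond. This is more
  conservative on low counts than shrinkage-based count models; the
  significant-gene set is an injectable argument downstream, so any
  external DE caller can replace it.
- **Single-cell DE** normalizes to a 10,000-count library then log1p,
  tests with the rank-sum statistic, and adjusts with BH by default
  (Bonferroni by flag, since marker-finding conventions differ).
- **Stability selection** subsamples without replacement (0.8 fraction;
  standard stability-selection practice where the resampling scheme is
  otherwise unstated) and uses the cross-validated one-standard-error
  penalty (`lambda.1se`) per iteration: the sparser CV rule keeps
  spurious genes out of the per-iteration support, which is what gives
  selection frequencies their signal/noise separation; `lambda.min` is
  available but admits noise genes into individual supports noticeably
  more often. Per-iteration seeds derive deterministically from the
  master seed.
- **Cox fits** use Efron tie handling throughout (better than Breslow at
  realistic tie rates) with a 1e-9 convergence tolerance in screening;
  screening failures (separation, non-convergence) are reported per gene
  without aborting.
- **Risk-score scoring across cohorts** defaults to per-cohort
  re-standardization (`"cohort"`), making score ranks invariant to
  gene-wise affine transforms — the pragmatic choice when training weights
  travel across platforms; `"train"` applies the training parameters.
- **IPCW AUC** weights cases by $1/\hat G(T_i^-)$ (left limit of the
  censoring Kaplan–Meier) and controls by $1/\hat G(t)$; with no censoring
  this reduces exactly to the empirical AUC of $\{T \le t\}$ vs
  $\{T > t\}$, which is also how binary-response ROC is exposed.
- **Meta-analysis** is fixed-effect (equal-effects) inverse-variance by
  default, random-effects (REML) behind a flag.
- **Calibration** bins subjects by predicted $S(t)$ (quantile bins,
  default 3 for small cohorts, automatically reduced when a bin would be
  empty), takes the within-bin Kaplan–Meier at $t$ as observed, and
  corrects optimism by the standard bootstrap-refit scheme (refit on each
  resample, compare apparent resample error with the refit model's error
  on the original cohort, subtract the mean difference).
- **Median dichotomization ties** go to low risk: deterministic and
  conservative toward the high-risk label.
- **Degenerate inputs** are refused with diagnostics rather than patched:
  fewer than 2 qualifying patients, constant genes in a Cox fit,
  undersized cell groups (named, with their sizes), missing model genes
  (listed; an opt-in drop mode exists for cross-platform use).

# Problem sizes used by the test suite

The packaged checks run the pipeline at sizes chosen to balance
Monte-Carlo resolution against a laptop-friendly runtime, and the key
recovery claims are calibrated at those sizes: variance components at 200
patients × 5 regions (±15%), Cox coefficient recovery at n = 2000
(±0.1–0.15), stability selection at 5 planted genes among 200 noise genes
with n = 500 and 100 subsample iterations (a scaled-down version of the
1,000-iteration default), the end-to-end study at 250 genes, two
multi-region cohorts of 30 patients, 60 tumor–normal pairs, and a
500-patient training cohort, and the log-rank type-I rate over 1,000 null
replicates.

# Known limitations

- The intra/inter score is one reasonable operationalization of
  region-level variance decomposition; method-of-moments or mixed-model
  variance components would weight patients differently.
- With few patients the inter score is itself noisy, and quadrant labels
  near the 75th percentile are unstable; consensus across cohorts
  mitigates but does not remove this.
- The "sustained" regional-trend call requires strictly monotone zone
  means; a gene rising N→B and flat B→T is "none" in both modes.
- Calibration's bootstrap refit assumes the model formula refits cleanly
  on resamples; tiny cohorts with rare events can lose bootstrap
  replicates (they are skipped, not imputed).
- The serialized JSON model carries coefficients and standardization only;
  absolute survival-probability prediction needs the in-session fit (the
  baseline hazard is not serialized).
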