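# evosig

Multi-region sequencing of a tumor shows that gene expression varies both
*within* a tumor (region to region) and *between* patients. `evosig` is an
R package for analysts who want to exploit that structure prognostically:
it scores every gene on the two heterogeneity axes, selects
evolution-related genes, builds a risk signature by stability-selected
penalized Cox regression, and evaluates the resulting risk score with the
standard survival toolkit. Everything runs on seeded synthetic cohorts
with known ground truth, so the whole pipeline is testable end to end
without any external data.

## The method in brief

For log2 expression $x_{g,p,r}$ of gene $g$ in region $r$ of patient $p$:

- **intra score** $= \operatorname{median}_p \operatorname{SD}_r(x_{g,p,\cdot})$,
- **inter score** $= \operatorname{SD}_p\big(\overline{x}_{g,p,\cdot}\big)$.

Genes strictly above the 75th percentile on *both* axes (quadrant Q1) are
intersected across cohorts into a consensus evolution-related set. The
signature candidates are the three-way intersection of that set with
paired tumor–normal DE genes ($|\log_2 FC| > 1$, BH-adjusted $p < 0.05$)
and univariate-Cox survival-associated genes ($p < 0.05$). Stability
selection (1,000 subsamples of 80%, L1-penalized Cox per subsample,
cross-validated penalty) keeps genes selected in over 85% of iterations;
a final multivariate Cox fit gives the risk score
$r_i = \sum_g \beta_g z_{g,i}$ on standardized expression, dichotomized at
each cohort's median. Evaluation: Kaplan–Meier / log-rank, Harrell's C,
IPCW time-dependent AUC, hazard-ratio meta-analysis, and calibrated
survival-probability prediction. A companion module classifies sustained
expression trends across ordered tissue zones (non-tumor → border → core)
in region-labelled single-cell counts.

## Worked example

```r
library(evosig)

# a complete synthetic study: 250 genes, 5 planted signature genes,
# two multi-region cohorts, 60 tumor-normal pairs, 500-patient training
# cohort, 100 stability-selection iterations
study <- run_synthetic_study(seed = 1)

study$selected
#> [1] "g0001" "g0002" "g0003" "g0004" "g0005"

study$model
#> <evosig_model> 5 genes; 500 samples, 307 events
#>  g0001  g0002  g0003  g0004  g0005
#>  0.854 -0.806  0.943 -0.930  0.837

round(c(high_risk_HR = study$high_risk_hr, C_index = study$c_index,
        AUC = study$auc, recovery = study$recovery), 3)
#> high_risk_HR      C_index          AUC     recovery
#>        8.438        0.850        0.927        1.000
```

All five planted genes (true per-SD log-hazards ±0.8–1.0) survive every
filter and are recovered (`recovery = 1`); their fitted coefficients match
the planted values. Dichotomizing the cohort at its median risk score
gives a high-vs-low hazard ratio of 8.4, a concordance of 0.85, and an
IPCW AUC of 0.93 at the median follow-up time. `generics::tidy(study$model)`
and `generics::glance(study$model)` return broom-style coefficient and fit
summaries; `plot_quadrants()`, `plot_km()`, `plot_selection_frequencies()`
and `plot_calibration()` draw the standard figures.

Individual stages are exposed as pipe-friendly functions, e.g.

```r
truth <- sim_truth(n_genes = 400, seed = 2)
mr <- gen_multiregion(truth, n_patients = 50, regions_range = c(3, 5), seed = 3)
quad <- heterogeneity_scores(mr$expr, mr$meta) |> classify_quadrants(q = 0.75)
table(quad$quadrant)
```

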