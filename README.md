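# scaledclust

Outcome-guided consensus clustering for heavily right-censored survival
cohorts.

## What problem this solves

In cohorts like oropharyngeal head-and-neck cancer populations, 70–80% of
subjects are censored for overall survival. Clustering the feature space
(clinical categories plus imaging-derived "radiomic" measurements) without
looking at the outcome usually recovers structure that is not prognostic,
while supervised methods that regress follow-up time directly mishandle the
censored majority.

`scaledclust` implements **supervised scaling**: every subject receives a
continuous outcome proxy — the martingale residual of a covariate-free Cox
model,

$$M_i = \delta_i - \hat\Lambda(t_i),$$

with $\hat\Lambda$ the Nelson–Aalen cumulative hazard — so censored subjects
contribute on equal footing. A linear regression of these residuals on the
min–max standardized features yields per-feature coefficients whose
magnitudes reweight the feature space; consensus k-medians clustering
(Manhattan distance, k-means++ seeding, resampled runs aggregated through
the consensus matrix $\mathcal{M}(i,j) = \sum_h M^{(h)} / \sum_h I^{(h)}$)
then extracts patient groups whose geometry reflects outcome relevance.

The package ships the complete experimental harness around the method:

* a synthetic-cohort generator with known two-group latent structure
  (configurable hazard ratio, feature separation, censoring fraction,
  MCAR missingness),
* preprocessing: predictive-mean-matching imputation by chained equations,
  min–max standardization with training-range reuse, zero-variance /
  correlation / anchor-correlation filters, RReliefF feature weighting,
* survival estimators: Nelson–Aalen, Kaplan–Meier, null-model martingale
  residuals, log-rank, Cox PH fits (Efron ties) with Breslow baselines,
* a leak-free 10-fold cross-validated pipeline with a
  standardization-only control branch,
* model comparison and metrics: AIC/AICc, likelihood-ratio tests, C-index
  with censoring-aware pair rules, IPCW Brier score and cumulative/dynamic
  AUC at a horizon, Nam–D'Agostino calibration, adjusted Rand index.

## Worked example

```r
library(scaledclust)

co  <- generate_cohort(cohort_config(seed = 1))   # 640 subjects, 2 latent groups
cfg <- pipeline_config(consensus_runs = 100, rrelieff_m = NULL, seed = 1)
cv  <- run_cv(co, cfg)                            # 10-fold CV, both branches

logrank_test(co$time, co$event, cv$labels_scaled)
adjusted_rand_index(cv$labels_scaled, co$latent_group)

clin   <- co$roles$feature[co$roles$role == "clinical"]
roster <- list(
  "Clin. Only"              = clin,
  "Clin & [Sc.] Cluster"    = c(clin, "cluster_scaled"),
  "Clin & [Stand.] Cluster" = c(clin, "cluster_standardized"))
compare_models(co, roster, cv, cfg, baseline = "Clin. Only")
```

Output (as printed by the code above):

```
log-rank chi-square 18.24, p = 1.9e-05
ARI to latent truth: scaled 0.644, standardization-only -0.001
Cox model comparison (negated AIC differences vs Clin. Only; positive = better):
                   model  p neg_delta_aic neg_delta_aicc     lrt_p
              Clin. Only 12         0.000         0.0000 1.000e+00
    Clin & [Sc.] Cluster 13        15.046        14.9620 3.649e-05
 Clin & [Stand.] Cluster 13         0.763         0.6791 9.647e-02
               auc  brier           c_index calibration
 0.6592 +/- 0.0235 0.1474 0.6111 +/- 0.0185       9.644
 0.6750 +/- 0.0232 0.1432 0.6567 +/- 0.0129      12.885
 0.6735 +/- 0.0247 0.1458 0.6230 +/- 0.0178      11.932
```

Reading it: the cross-validated **scaled** cluster labels recover the
latent risk groups (ARI 0.64), separate the Kaplan–Meier curves decisively
(log-rank p ≈ 2×10⁻⁵), and added to the clinical Cox model improve the
negated AIC difference by +15 (≥ 3 is meaningful) with LRT p ≈ 4×10⁻⁵ and
a higher concordance (0.657 vs 0.611). The **standardization-only** labels
— same pipeline without the supervised scaling step — recover nothing
(ARI ≈ 0) and add no model value (+0.76, LRT p = 0.10). That contrast is
the method's reason to exist.

A thin CLI wraps the same functions
(`generate` / `run` / `compare` / `metrics`):

```sh
Rscript inst/cli/scaledclust.R generate --config cfg.yaml --seed 1 --out-dir out/
Rscript inst/cli/scaledclust.R run --cohort out/cohort.csv --seed 1 --out-dir out/
```

See `vignettes/supervised-scaling.Rmd` for the model, its assumptions, all
tunable parameters, and two important caveats established by the package's
own experiments (partial recovery at ~80% censoring; anti-conservatism of
full-data refits with cross-validated supervised labels under the null).

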