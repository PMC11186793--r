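# immunofactors

Multi-omic factor analysis of longitudinal immune profiles.

## What this is for

Acute coronary syndrome (ACS) sets off a time-resolved, system-wide immune
program that shows up simultaneously in cell-type-specific gene expression,
circulating cytokines, the plasma proteome, the neutrophil transcriptome
and routine clinical markers. `immunofactors` is for analysts who want to
integrate such longitudinal multi-omic cohorts into a small number of
interpretable latent **factors**, follow those factors over the clinical
time course, replicate them in an external cohort, and test whether they
predict the recovery of cardiac function — all as a scripted, reproducible
pipeline rather than a one-off notebook.

The package covers the full workflow:

* view-specific harmonization (pseudobulk aggregation with prevalence
  filters, cytokine out-of-range handling, neutrophil count filtering,
  left-censored proteomics imputation, quantile and inverse-normal
  normalization, CLR composition analysis);
* a Gaussian **group factor model with automatic relevance determination
  (ARD)**, fitted by expectation–maximization under per-view
  missing-sample masks;
* variance decomposition, factor-weight feature ranking, trajectory
  summaries;
* cross-cohort **right-inverse projection** of new samples onto existing
  factors;
* rank-sum **pathway enrichment** on factor weights across all views;
* prior-guided **ligand–receptor–target communication scoring** with an
  optional one-timepoint lag;
* **outcome prediction** (min–max scaled ROC, cross-validated lasso
  logistic regression, reduced-feature logistic models);
* a synthetic multiomic cohort generator with known ground truth, so the
  whole pipeline is testable without patient data.

## The model

Each modality or cell-type cluster is a view $m$ with data $Y_m$
(samples × features). The model is

$$y_{mn} = W_m z_n + \varepsilon_{mn},\qquad
\varepsilon_{mn} \sim \mathcal N(0, \tau_m^{-1} I),\qquad
z_n \sim \mathcal N(0, I_K),\qquad
w_{mk} \sim \mathcal N(0, \alpha_{mk}^{-1} I),$$

where the ARD precisions $\alpha_{mk}$ prune factor–view pairs without
signal. The E-step uses the exact Gaussian posterior of $z_n$ over the
views present for each sample; W, τ and α update in closed form; the ELBO
trace is monotone and initialization is deterministic (SVD), so fits are
bit-reproducible. New cohorts are projected by the right inverse
$Z = Y W^\top (W W^\top)^{-1}$ on matched features. Details, assumptions
and numerical choices are in `vignettes/methods.Rmd`.

## Worked example

Generate a synthetic cohort with a planted ischemia-trajectory factor and a
planted outcome factor, harmonize it, fit the model and inspect what comes
back:

```r
library(immunofactors)

sim     <- generate_cohort(cohort_config(seed = 42))
dataset <- preprocess_cohort(sim$cohort)
fit     <- fit_gfa(dataset, K = 10)
fit
#> <ifa_gfa> K = 10 factors, 48 samples, 6 views; 214 iterations (converged)

variance_explained(fit, dataset)
#> <ifa_variance> fraction of view variance explained
#>          view       F1       F2       F3       F4       F5 ...
#> 1    cluster0 2.80e-01 2.68e-01 2.43e-01 1.60e-05 9.23e-02
#> 2    cluster1 1.21e-05 2.85e-01 2.22e-01 3.25e-01 5.53e-06
#> 3    cluster2 4.43e-01 1.64e-05 3.87e-01 4.70e-06 7.29e-06
#> 4   cytokines 1.58e-05 3.65e-01 4.09e-06 3.66e-01 6.32e-06
#> 5  proteomics 2.17e-01 1.40e-05 2.04e-01 2.19e-01 4.78e-06
#> 6 neutrophils 2.55e-01 2.80e-01 2.72e-05 1.56e-01 7.06e-06
```

Four factors carry real variance (0.15–0.44 per view where active, ~1e-5
where the generator planted silence); the remaining six are pruned by the
ARD prior. Because the generator ships its ground truth, we can ask which
fitted factor is the planted trajectory:

```r
# pruned factors have constant scores, hence the suppressed sd-zero warning
cors   <- suppressWarnings(
  cor(fit$Z, sim$truth$Z_true[rownames(fit$Z), sim$truth$trajectory_factor]))
k_traj <- which.max(abs(cors))
sprintf("trajectory factor recovered as F%d (|r| = %.3f)", k_traj, abs(cors[k_traj]))
#> "trajectory factor recovered as F4 (|r| = 0.964)"

summarize_trajectory(fit$Z, dataset$meta, k_traj)
#> # A tibble: 6 × 5
#>   group       timepoint     n   mean   sem
#> 1 CCS         TP0           8 -1.96  0.244
#> 2 non_CCS     TP0           8 -2.45  0.278
#> 3 sterile_ACS TP1           8  0.732 0.320
#> 4 sterile_ACS TP2           8  3.40  0.175
#> 5 sterile_ACS TP3           8  1.76  0.235
#> 6 sterile_ACS TP4           8 -1.59  0.428
```

The recovered factor rises from admission (TP1) to a peak shortly after
(TP2) and decays toward discharge (TP4), while both control groups sit
flat — exactly the planted rise-then-decay ischemia trajectory. The same
matching for the planted outcome factor, evaluated as a classifier of good
vs poor recovery at admission:

```r
cors_out <- suppressWarnings(
  cor(fit$Z, sim$truth$Z_true[rownames(fit$Z), sim$truth$outcome_factor]))
k_out  <- which.max(abs(cors_out))
meta   <- label_outcome(dataset$meta, munich_rule())
tp1    <- meta$timepoint == "TP1" & meta$outcome != "unknown"
scores <- -sign(cors_out[k_out]) * fit$Z[meta$sample_id[tp1], k_out]
roc_auc(minmax_scale(scores), meta$outcome[tp1], positive = "poor")
#> <ifa_roc> AUC = 0.750 (4 positive vs 4 negative)
```

At the default cohort size (4 vs 4 patients at TP1) the planted 1.5 SD
shift yields AUC 0.75; the test suite runs the same check at 12 vs 12
patients with a stronger planted effect, where the factor discriminates
with AUC > 0.8 across seeds. `autoplot()` methods exist for variance
decompositions and ROC curves, `plot_trajectory()` for factor time
courses, and `tidy()`/`glance()` for every fitted object.

`run_pipeline(config, out_dir)` chains the whole thing — simulate,
harmonize, fit, decompose, rank, correlate ligands with targets, predict —
into a run directory with a hash-chained `manifest.json`, reproducible
bit-for-bit from the configuration and seed.

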