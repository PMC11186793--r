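---
title: "Methods: multi-omic factor analysis of longitudinal immune profiles"
author: "immunofactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic factor analysis of longitudinal immune profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunofactors)
```

## The problem

Acute coronary syndrome (ACS) triggers a coordinated, time-resolved immune
response that is visible simultaneously in circulating cell-type-specific
gene expression, plasma cytokines, the plasma proteome, the neutrophil
transcriptome and routine clinical markers. No single modality captures the
program; the analysis question is how to extract shared axes of inter-patient
variation ("factors") from all modalities at once, follow them over the
in-hospital time course (TP1 admission through TP4 discharge, with
single-timepoint chronic and ruled-out coronary syndrome controls at TP0),
replicate them in an external cohort, and test whether they predict the
recovery of cardiac function.

`immunofactors` implements that workflow as a reusable, tested pipeline:
view-specific harmonization, a multi-view (group) factor model, variance
decomposition and feature ranking, cross-cohort projection, pathway
enrichment on factor weights, prior-guided ligand–receptor–target
communication scoring, and penalized logistic outcome prediction. Because
patient-level data of this kind cannot ship with a package, a synthetic
cohort generator with fully known latent structure accompanies the pipeline
and is itself first-class, tested code: every downstream claim the test
suite makes is a recovery statement about structure the generator planted.

## The factor model

Each modality (and each cell-type cluster's pseudobulk profile) is a *view*
$m$ with feature matrix $Y_m$ (samples × features). The model is Gaussian
group factor analysis with automatic relevance determination (ARD):

$$y_{mn} = W_m z_n + \varepsilon_{mn},\qquad
\varepsilon_{mn}\sim\mathcal N(0,\tau_m^{-1}I),\qquad
z_n\sim\mathcal N(0,I_K),\qquad
w_{mk}\sim\mathcal N(0,\alpha_{mk}^{-1}I_{D_m}).$$

The per-(view, factor) ARD precision $\alpha_{mk}$ shrinks factor–view pairs
that carry no signal toward zero weight, which is what makes the per-view
variance decomposition interpretable and superfluous factors harmless.
Estimation is expectation–maximization: the E-step computes the exact
Gaussian posterior of $z_n$ given whichever views are present for that
sample (absent views simply contribute nothing, so per-view missing samples
are handled natively), and the M-step updates $W_m$, $\tau_m$ and
$\alpha_{mk}$ in closed form, with $\alpha$ capped at $10^6$ to keep the
objective bounded. The trace records the evidence lower bound, which is
non-decreasing by construction; the fit stops when its relative change
falls below `tol` (default $10^{-6}$) or after `max_iter` (default 50,000,
far beyond what the EM needs — convergence is typically a few hundred
iterations).

Unlike the published multi-omics factor analysis implementations, no
spike-and-slab feature-level sparsity is used: the quantities the pipeline
consumes downstream — variance decomposition, absolute-weight feature
ranking, and right-inverse projection — are defined on $(Z, W)$ regardless,
and the Gaussian ARD model keeps the fit deterministic and fast.
Initialization is deterministic (left singular vectors of the concatenated,
per-view-scaled data, with a fixed sign convention), so a fit never depends
on a random seed; `fit_gfa()`'s `seed` argument exists only for interface
stability. Factors are ordered by total explained sum of squares and signed
so each factor's largest-magnitude weight is positive.

Variance fractions use uncentered sums of squares,
$1-\sum(y-z_kw_k^\top)^2/\sum y^2$; this is valid because every view is
inverse-normal transformed (feature means $\approx 0$) before fitting.

## Harmonization rules

Each view has its own recipe, applied before the model sees the data:

* **Pseudobulk** (`pseudobulk()`): per (sample, cluster), the mean raw count
  over cells; each sample row is then rescaled so all rows of a cluster view
  share the same total (mean of totals), removing sequencing-depth
  differences. (Sample, cluster) pairs without cells are masked absent, not
  zero-filled. Genes enter a cluster view only when reliably expressed:
  prevalence filters are OR-combinations of strict (pct, n) pairs —
  (50, 1200) | (40, 3000) for the primary cohort recipe, (30, 1000) |
  (20, 2500) for the validation-cohort recipe, and a laxer default for the
  synthetic scale. Retained views are log(x+1) transformed and
  quantile-normalized across samples (reference = mean of order statistics;
  ties share the mean of their spanned reference values).
* **Cytokines** (`preprocess_cytokines()`): out-of-range (OOR) sentinel
  readings are preserved distinctly by the reader; analytes with valid
  values in fewer than 20% of samples are removed *before* substitution
  (an OOR cell counts as invalid for this rule); then OOR → 0 and
  log(x+1).
* **Neutrophil counts** (`preprocess_neutrophils()`), in order:
  drop mitochondrial/ribosomal prefixes; drop genes expressed in <80% of
  samples; drop samples with reads in <90% of the remaining genes;
  equal-total depth scaling; log(x+1); drop genes below the 25% variance
  quantile (linear-interpolation quantile; strictly-below removed, ties at
  the threshold kept); quantile normalization. Every decision is logged.
* **Proteomics** (`preprocess_proteomics()`): proteins, then samples, with
  <80% valid values are removed (protein rule first); each protein is
  median-centered; missing entries are drawn from
  $\mathcal N(\mu_p - 1.8\sigma_p,\,(0.3\sigma_p)^2)$ — the classic
  downshifted-Gaussian imputation for left-censored intensity dropout; the
  width 0.3 follows the common proteomics convention since only the
  downshift is conventionally reported. Deterministic given a seed.
* **Clinical markers** (`preprocess_clinical()`): log(x+1); negative values
  are a hard error. The pseudocount unifies zero handling across the
  log-transformed views.
* **Inverse-normal transform** (`inverse_normal_transform()`): per feature,
  values map to $\Phi^{-1}(r/(n+1))$ with average ranks for ties, computed
  over present samples; constant features map to 0. The $r/(n+1)$ offset is
  a deliberate choice where the convention is not fixed; any strictly
  monotone transform of a feature yields identical output.
* **Composition** (`clr_composition()`): per-sample cluster proportions with
  a 0.5-cell pseudocount (guarding empty clusters), then the centered
  log-ratio; rows sum to zero.

## Cross-cohort projection

A fitted model transfers to an external cohort by exact feature-id
intersection within whitelisted views (`match_features()`; cross-cohort
cluster naming is reduced to a user-supplied mapping table), after the
target has been preprocessed with the *source* recipe. Projection is the
right inverse, $Z = Y W^\top (W W^\top)^{-1}$, computed jointly over all
matched features. $WW^\top$ must be well-conditioned (guard at condition
number $10^{10}$): factors pruned by ARD carry near-zero weights and must
be excluded by the caller before projecting, which the tests demonstrate.
Trajectory summaries (per group/timepoint mean ± SEM) can be sign-aligned
to a source-cohort reference because a factor's sign is a convention.

## Enrichment, communication, prediction

**Enrichment** extends each pathway's gene set to all `view::gene` features
whose symbol it contains; coverage is the fraction of pathway genes present
anywhere in the feature universe, with pathways under 20% coverage removed
(strictly below). The test statistic is a two-sided Wilcoxon rank-sum of
set vs background scores — signed weights for the positive/negative modes
(restricted to features of that sign), absolute weights for the joint mode
(an explicit choice; the joint mode's handedness is not conventionally
fixed) — exact when both groups have ≤10 tie-free values, normal
approximation with tie correction otherwise, with Benjamini–Hochberg
adjustment within each direction.

**Communication** starts from factor-defined targets (top 1% of features by
|weight|, split by sign), keeps (ligand, target) pairs whose prior
regulatory potential reaches the 97% quantile of the whole matrix
(inclusive at the boundary; zeros included in the quantile), requires — when
the target sits in a cell-type cluster view — a receptor of the ligand
reliably measured in that cluster ((pct > 30 & n > 600) | (pct > 10 &
n > 1200)), and scores pairs by Spearman correlation across samples,
keeping $|\rho| \ge 0.4$. The lagged mode pairs each ACS patient's ligand
at TP1/TP2/TP3 with the target at TP2/TP3/TP4. Correlations with fewer
than 5 usable observations are dropped — a minimal-information guard the
analysis otherwise leaves implicit.

**Prediction**: outcome labels derive from the ejection-fraction change,
with the stable case resolved per cohort convention (`munich_rule()`:
stable = good; `groningen_rule()`: stable = poor) — the two conventions are
preserved verbatim rather than harmonized. Scores are min–max scaled (a
monotone map, so AUC is unchanged) and evaluated by rank-statistic ROC AUC.
The lasso classifier is L1 logistic regression over a 100-value log-spaced
path down to $10^{-4}\lambda_{\max}$ with 8-fold cross-validation at
`lambda.min` under mean binomial deviance; fold assignment is deterministic
and class-stratified by default (a stability choice at n ≈ 20; a flag
restores unstratified folds). The reduced-feature model is plain IRLS
logistic regression with perfect separation treated as an error.

## What the synthetic generator emulates

`cohort_config()` defaults define the study conditions the suite tests
under: 8 patients per group (sterile ACS at TP1–TP4; CCS and non-CCS
controls at TP0), 4 true factors, 6 factor views (3 cluster pseudobulk
views of 50-gene panels plus shared receptor genes, 40 cytokines, 60
proteins, 80 neutrophil genes), per-feature unit signal scale with
view noise SD 0.5 (signal-to-noise ratio 2), 10% missing samples per view,
5% OOR cytokine readings (the lowest values, as in a real calibration
range), 15% left-censored proteomics dropout (missingness logistic in the
within-protein z-score), negative-binomial counts with dispersion 0.1, and
a log-normal(0, 0.3) per-cell library-size factor.

Planted structure: the trajectory factor follows a rise-then-decay pattern
over TP1→TP4 (peak at TP2) and idles near zero for controls; the outcome
factor is shifted downward at TP1 by `outcome_effect` (in SD units) for
poor-outcome patients, with balanced good/poor labels encoded in the sign
of ΔEF; the first cluster's abundance declines over the ACS course
(timepoint-dependent Dirichlet concentration) to exercise the CLR analysis;
each factor is silent in exactly two views, with distinct silent-view pairs
per factor — identical activity patterns would leave a factor pair
rotationally unidentifiable — so that planted active pairs hold a clearly
non-trivial variance share (~0.2–0.3) and silent pairs are exactly zero in
truth; three ligand–target pairs (a trajectory-loaded cytokine and a
trajectory-loaded cluster gene) receive prior potential above the 97%
quantile and a receptor edge expressed in the target cluster, amid i.i.d.
decoys.

The generator does **not** emulate: read-level artifacts (no FASTQ,
doublets or hashing), batch effects between libraries, cell-level quality
gradients, correlated noise across views, non-linear factor effects, or
realistic feature-feature correlation beyond the planted factors. Passing
tests therefore demonstrate that the pipeline recovers linear latent
structure under realistic missingness, censoring and count noise — not that
it is robust to every artifact of real cohorts.

## Evaluation conditions and problem sizes

The recovery checks run the full pipeline on the default cohort
(48 samples, ~330 post-filter features over 6 views) across 10 generator
seeds with K = 10 fits; the robustness check compares K ∈ {5, 10, 15, 20}
on one cohort. Outcome-prediction checks enlarge the ACS arm to 24 patients
(12 good vs 12 poor) and instantiate the planted TP1 shift at 2.5 SD — a
strong, cleanly separable effect chosen so the discrimination checks test
the pipeline rather than the overlap of two nearby distributions; the null
checks set the shift to zero. Cross-cohort checks generate a second cohort
sharing the true weight matrices (fresh patients, scores, noise and
artefacts), train on cohort A (lasso over the intersection of two fits'
top features at TP1) and evaluate on projected cohort B. These sizes keep
any single check within a few minutes on one core while leaving the
statistical margins wide.

## Numerical choices and degenerate inputs

* EM: ELBO evaluated after each E-step with the parameters that produced
  it, guaranteeing a monotone trace; $\alpha \le 10^6$; residual floors at
  $10^{-12}$ guard $\tau$.
* A constant feature inverse-normal transforms to all zeros; a constant
  protein with missing entries imputes the constant $\mu_p - 1.8\sigma_p$
  (σ = 0); constant input to `minmax_scale()` returns 0.5 with a warning.
* Ties: average ranks everywhere (inverse-normal, Spearman, ROC);
  quantile-normalization ties share the mean of spanned reference values;
  all prevalence-filter inequalities are strict, coverage and potential
  thresholds inclusive.
* Readers refuse silent coercion: any non-numeric cell that is neither
  empty nor the OOR token names its row and column; duplicate ids are
  errors; an empty view or a sample absent from metadata aborts alignment.
* Serialization is plain TSV + JSON manifest at `%.17g` precision
  (round-trips below $10^{-12}$), versioned, language-neutral and
  diff-able — deliberately so the projection workflow can reuse weights
  outside R.

## Known limitations

The Gaussian ARD model has no feature-level sparsity, so single-feature
interpretation of weights is softer than under spike-and-slab priors; the
EM returns posterior means of $Z$, not samples, so factor-score uncertainty
is not propagated downstream; projection requires the pruned-factor subset
to be chosen by the caller; the enrichment null is the permutation of
feature labels implied by the rank-sum test, which ignores inter-feature
correlation and is therefore anti-conservative on strongly correlated
panels; and the generator's linearity means the suite cannot detect
failures specific to non-linear immune dynamics.
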