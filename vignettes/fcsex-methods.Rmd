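---
title: "Methods: sex differences in resting-state functional network topology"
author: "fcsex package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex differences in resting-state functional network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsex)
```

## The analysis in one page

`fcsex` implements a complete group-level analysis of sex differences in
resting-state functional brain connectomes, starting from regional fMRI time
series (the pipeline deliberately does not touch image preprocessing):

1. **Functional connectivity.** For each session, Pearson correlations
   between the 94 regional time series are Fisher r-to-z transformed
   (`compute_fc()`). Correlations are clipped at `|r| <= 1 - 1e-7` before
   `atanh` so degenerate (duplicated) series cannot produce infinite edges.
2. **Proportional thresholding.** Each FC matrix is swept over 46 sparsity
   levels, 0.05 to 0.50 in steps of 0.01 (`sparsity_grid()`): at level *s*
   the strongest `round(s * N(N-1)/2)` positive edges are retained *with
   their weights* — graphs are never binarized. Negative Fisher-z edges are
   excluded before ranking, because nodal strength and geometric-mean
   triangle products presuppose nonnegative weights; this is the dominant
   convention for proportional thresholding and is configurable in spirit:
   the thresholding function accepts any symmetric matrix, so users can
   pre-transform (e.g. absolute value) if they prefer another convention.
3. **Network metrics.** On every thresholded graph three weighted metrics
   are computed per node (`session_metrics()`): strength
   `k_i = sum_j w_ij`; efficiency `E_i = mean_j 1/d_ij` with weighted
   shortest-path lengths under edge length `1/w`; and the clustering
   coefficient `C_i = 2 t_i / (deg_i (deg_i - 1))` with geometric-mean
   triangle intensity `t_i = 1/2 sum_{j,h} (w'_ij w'_jh w'_hi)^{1/3}` on
   max-normalised weights `w' = w / max(w)`. Global metrics are node means.
   Values are integrated over the sparsity grid (unweighted mean over the 46
   levels) and z-scored across all sessions pooled.
4. **Group inference.** Session-level metrics are adjusted with the linear
   mixed model `metric ~ sex + age + handedness + education + APOE4 +
   (1 | subject)` fitted by REML; the adjusted value subtracts the centred
   nuisance fixed effects and the predicted subject intercept while the sex
   term and residual are retained (`fit_lme_adjust()`). Two-sided
   pooled-variance t-tests compare women against men, Bonferroni-corrected
   over 3 global metrics or 94 regions per regional metric family
   (`sex_ttest()`).
5. **Network-based statistic.** Edge-wise sex contrasts on adjusted
   inter-regional FC are thresholded at raw one-sided p < 0.005; connected
   components of supra-threshold edges are assigned family-wise-error
   corrected p-values from the permutation distribution of the maximal
   component extent, permuting sex labels at the *subject* level
   (`nbs_permutation()`).

A synthetic-cohort generator (`sim_config()`, `simulate_study()`) emulates
the data structure this analysis expects, so that every stage — including
its error control — is testable without access to restricted imaging data.

## Design choices that were genuinely open

**Global aggregation of strength.** The metric-table convention writes
global strength as a node *sum* in some sources and a node *mean* in others.
The package computes the mean for all three metrics so they share a scale,
and exposes `global = "sum"` as an option. The two differ by the fixed
factor N, so z-scored group inference is identical under either.

**Clustering denominator.** With strength in the denominator, the weighted
clustering coefficient is not bounded by 1 and loses its "proportion of
neighbour pairs" reading. The implementation defaults to the binary degree
`deg_i` (the standard geometric-mean convention) and offers
`denominator = "strength"` as a switch.

**Edge length for shortest paths.** `1/w` is the default (the dominant
convention for weighted efficiency); `-log(w)` is available behind the
`length` argument.

**Integration over sparsity.** The unweighted mean over the 46 grid levels
is used; trapezoid area-under-curve (divided by the grid range) is available
and differs only in the half-weighting of the two endpoints. For any fixed
grid the two are affine-equivalent and cannot change test significance.

**Amyloid boundary and window.** A session is amyloid-positive only when its
composite SUVR strictly exceeds 1.11 ("above" the threshold), negative at or
below it, and unknown when no PET scan falls within 365 days of the MRI;
when several qualify, the nearest by date is used.

**Bonferroni families.** 94 regions within each regional metric family;
3 tests for the global metrics.

**Tie-breaking and rounding.** Proportional thresholding ranks by descending
weight with ties broken in `(i, j)` index order, and edge counts use
round-half-away-from-zero — both so that edge sets are bit-stable across
platforms and nested across the grid.

## The permutation engine and exchangeability

Repeated sessions make session labels non-exchangeable: all sessions of a
subject carry the same sex label and share that subject's stable network
traits. The NBS therefore permutes at the subject level — all sessions of a
subject move together — and the package demonstrates in its test suite that
a session-level permutation scheme understates the width of the null
distribution of the maximal component extent on cohorts with strong subject
effects.

Two details of the default (Freedman–Lane-style) shortcut matter and were
learned the hard way during development:

* **Subject intercepts stay in the data.** The predicted subject intercepts
  of the mixed model are estimated around the observed sex-group means.
  Subtracting them before permuting would bake the observed labelling into
  the "adjusted" data and makes the test wildly anticonservative. Instead
  the subject effects remain, and the subject-level permutation accounts for
  them exactly.
* **Sex is left out of the nuisance-estimation model.** If the covariate
  coefficients are estimated jointly with sex, the residualised data keep
  full variance along the observed sex contrast but lose variance along
  permuted contrasts that correlate with covariates — again privileging the
  observed labelling. The shortcut therefore residualises on the reduced
  (sex-free) mixed model, the classic Freedman–Lane construction.

`exact = TRUE` refits the full mixed-model adjustment (sex in the model,
subject intercepts removed) under every permutation; it is slow and is
intended for verification at small scale. FWE p-values use the add-one
estimator `(1 + b)/(1 + m)` and are never zero; when fewer distinct
subject-label assignments exist than requested permutations, all are
enumerated.

## What the synthetic cohort emulates

The generator reproduces the statistical structure the analysis assumes,
with defaults matching a cognitively normal aging cohort:

* **Cohort composition.** 48 men and 74 women; 1–3 sessions per subject with
  mean ≈ 1.7; per-sex covariate distributions (age 72.2 ± 4.3 / 72.6 ± 4.5
  years, education 17.7 ± 2.2 / 16.3 ± 2.3 years, left-handedness ≈ 10% /
  15%, APOE4 carriage 25% / 36%, session-level ADAS-Cog ≈ 5.7 ± 2.3 /
  5.5 ± 2.2). Note the education imbalance is deliberate: the analysis must
  adjust for sex-correlated covariates, not assume them away.
* **Time series.** Zero-mean multivariate Gaussian with per-region AR(1)
  autocorrelation (default coefficient 0.3, the same for all regions so the
  cross-correlation target is preserved), T = 192 volumes by default —
  representative of 140–200-volume echo-planar runs; only the correlation
  estimates matter downstream. The group covariance is a block-factor model
  (six community blocks plus a global factor; mean off-diagonal correlation
  ≈ 0.3), which guarantees positive definiteness and gives the sparsity
  sweep realistic heterogeneity.
* **The implanted sex effect.** The female group's off-diagonal covariance
  is the male group's times `sex_effect_scale`; regions listed in
  `reversal_regions` receive the inverted factor, emulating subcortical
  structures where women show higher connectivity. Because
  `R_women = s * R_men + (1 - s) * I` for `s < 1`, the scaled matrix stays
  positive definite by construction; inverted-factor entries are capped and
  repaired by diagonal loading when needed.
* **Subject random effects.** Each subject carries a multiplicative factor
  on off-diagonal covariance, `exp(N(0, subject_effect_sd))` (default SD
  0.05), inducing within-subject correlation of the downstream metrics. At
  the default run length this yields test–retest intraclass correlations of
  the global metrics around 0.2 — the low-to-moderate reliability plausible
  for sessions collected ~6–12 months apart in an aging cohort. The SD was
  fixed against that reliability anchor.
* **Amyloid PET.** Composite SUVR is a two-component Gaussian mixture
  (negative ≈ 1.00 ± 0.05, positive ≈ 1.30 ± 0.10) with APOE4 carriers
  drawn amyloid-positive more often (60% vs 27%); ~6% of sessions lack a
  PET and ~5% have one outside the 1-year window, emulating
  unknown-status sessions. These magnitudes exercise the classification and
  ANOVA stages; they are artifact choices, not empirical claims.
* **Cognition.** Scores are per-sex affine functions of a chosen global
  metric plus Gaussian noise, giving known ground truth for the per-group
  regression and slope-difference stages.

What the generator does **not** emulate: voxelwise signals, scanner noise
spectra, motion artifacts, spatially structured residual correlations
beyond the block-factor model, and any nonstationarity within a run. A
passing test suite therefore certifies the statistical machinery — error
control, direction and magnitude recovery under the stated model — not the
behaviour of the pipeline on real fMRI, where preprocessing quality and
unmodelled confounds dominate.

## Numerical and degenerate-input behaviour

* Constant (zero-variance) regional series abort FC construction with the
  offending region named; constant covariate columns (e.g. no left-handers
  in a small draw) are dropped from the adjustment model.
* If fewer positive edges exist than a sparsity level requests, all are
  retained with a warning; an all-negative FC matrix yields an empty graph.
* Unreachable node pairs contribute zero to efficiency; nodes of degree < 2
  have clustering 0; the empty graph has all metrics 0.
* Mixed-model fits fall back REML → ML → fixed-effects-only (with a
  warning); edges whose variance is numerically zero are passed through
  with p = 1 and counted.
* Thresholding, metric sweeps and component extraction are deterministic;
  all simulation and permutation randomness derives from explicit integer
  seeds, with per-session sub-seeds below 2^31.

## Problem sizes used in the packaged simulations

The package's own simulation studies (test suite and acceptance script) run
at reduced scale chosen to keep the full statistical design intact: cohorts
of 48 + 74 subjects (the default composition) with 12–30 regions and 60–100
timepoints per session, 500 replicates for the type-I study of the global
contrasts, 200 replicates × 500 permutations for the NBS calibration study,
and 25 replicates for power/direction recovery. Region count enters the
metrics only through graph size, so the error-control properties being
checked do not depend on using the full 94-region atlas; the full-scale
configuration remains the default for data analysis.

## Known limitations

* The two-step "adjust, then t-test" scheme inherited by the metric-level
  contrasts treats session-level adjusted values as independent
  observations. With repeated sessions and non-trivial subject variance this
  is mildly anticonservative even after subject-intercept removal (BLUP
  shrinkage leaves part of the between-subject noise in the group contrast
  while deflating the within-group spread); the package's type-I simulation
  quantifies this at its study conditions. The NBS stage does not share this
  issue — its subject-level permutation is calibrated by construction — and
  a fully calibrated metric-level alternative is the mixed model's own sex
  term with Satterthwaite/Kenward–Roger degrees of freedom.
* Bonferroni correction over regions is conservative under the strong
  spatial dependence of nodal metrics.
* The macroarea mapping shipped in `inst/extdata/` approximates standard
  lobar anatomy for the 94-region atlas; it is editable configuration, not a
  canonical atlas product.
* Negative-edge handling (exclusion before ranking) is a convention, not a
  finding; conclusions about metrics that are sensitive to negative
  correlations require a different connectivity definition altogether.
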