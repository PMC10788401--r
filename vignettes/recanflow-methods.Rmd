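---
title: "Methods: spatiotemporal hemodynamic features and recanalization modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal hemodynamic features and recanalization modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recanflow)
```

## The problem and the quantities

After coil embolization of an intracranial aneurysm, a minority of
aneurysms recanalize during follow-up. Hemodynamic quantities computed
from time-resolved flow simulations — dome velocity, wall shear stress,
static and dynamic pressure at the neck plane, and, on the *virtual
post-coiling model* (the vessel with the dome computationally removed),
the neck pressure excess — are candidate predictors of that outcome. The
central score is the dimensionless pressure difference

$$\mathrm{PD} = \frac{P - P_\mathrm{inlet}}{\tfrac12 \rho v_\mathrm{inlet}^2},
\qquad \rho = 1100~\mathrm{kg/m^3},$$

with $v_\mathrm{inlet}$, $P_\mathrm{inlet}$ spatiotemporally averaged
inlet quantities. Because a field is a function of space and time, it
admits many scalarizations: this package crosses two spatial reductions
(area-weighted average `ave`, maximum `max`) with seven temporal
descriptors (time-average `a`, `median`, `q1`, `q2`, `max`, `min`,
sample `std`) for six field parameters, plus the seven temporal
descriptors of the inflow rate ratio
$\mathrm{FR}(t) = Q_\mathrm{neck}(t)/Q_\mathrm{inlet}(t)$ —
$6 \times 14 + 7 = 91$ hemodynamic features. volvel, WSS, P and Pdyn are
made dimensionless with the time-constant inlet scalars
($v_\mathrm{inlet}$, $\mathrm{WSS}_\mathrm{inlet}$, $P_\mathrm{inlet}$,
and $\tfrac12\rho v_\mathrm{inlet}^2$ respectively — the dynamic-pressure
normalizer is chosen for dimensional consistency with the PD
denominator); PP remains in Pa and PD is dimensionless by construction.

## The synthetic cohort generator

The clinical cohort behind this design (66 aneurysms, 57 stable and 9
recanalized) is not publicly deposited, so the package generates
synthetic cohorts with the statistical structure the analysis assumes.
Each patient's field for parameter $X$ is

$$X_{s,t} = m_X \cdot \frac{w(t)}{\bar w} \cdot h_s \cdot
(1 + \sigma_t \varepsilon_{s,t}),$$

where $w(t)$ is a strictly positive truncated-Fourier pulse (three
default harmonics, baseline 1, cycle 0.9 s, two cycles = 1.8 s, sampled
every 0.01 s → 181 points), $h_s$ is a fixed spatial profile with unit
mean and coefficient of variation `spatial_cv` (default 0.15), and
$\varepsilon$ is Gaussian noise with scale `temporal_cv` (default 0.05).
The patient-level target $m_X$ is an independent draw from the group's
(mean, SD) — the published significant-feature summaries provide the
volvel and PD targets (stable/recanalized means 0.441/0.299 and
0.361/0.903) and the FR direction and scale; P, Pdyn and WSS carry no
group effect (1.0 ± 0.08, 0.5 ± 0.25, 1.1 ± 0.5, chosen once as
physiologically plausible dimensionless levels). Draws are truncated at
zero for the non-negative parameters (volvel, WSS, Pdyn, FR); at the
default targets the truncation bias is negligible (≤ 2.8 SD from zero).

Three constructions deserve explanation:

- **PP/PD coupling.** Feature extraction *derives* PD from the
  virtual-model neck pressure (PD = PP divided by the inlet dynamic
  pressure), so PP and PD cannot be independent draws. PD is the primary
  draw — it is the parameter with published group summaries — and the
  neck pressure field is built as
  $P_\mathrm{inlet} + \mathrm{PD}\cdot\tfrac12\rho v_\mathrm{inlet}^2$,
  so the extracted PD reproduces its target exactly and PP inherits the
  implied pascal scale.
- **Pdyn round-trip.** The generator draws the dimensionless Pdyn target
  and stores the implied neck-plane velocity
  $v = v_\mathrm{inlet}\sqrt{\mathrm{Pdyn}^*}$; extraction then computes
  $\tfrac12\rho v^2$ and normalizes, recovering the target.
- **FR as a pure time series.** FR never had a spatial dimension in the
  analysis, so it is generated directly as a small positive series with
  multiplicative lognormal temporal noise (unit mean), and the neck
  inflow is stored as $\mathrm{FR}(t)\,Q_\mathrm{inlet}(t)$.

Inlet references use a fixed pressure reference of 100 Pa, inlet velocity
0.25 m/s with mild patient jitter (SD 0.03), inlet WSS 2 Pa, and inlet
flow 4 ml/s — typical parent-artery values; the inflow *waveform* is
shared by all patients, mirroring uniform boundary conditions.
Morphometry uses the published group summaries where available (max
size, height, neck area) and plausible dependent constructions elsewhere
(ellipsoidal volume, ~25% coil packing density).

What the generator does **not** emulate: spatial autocorrelation on a
real mesh (samples are exchangeable), inter-parameter correlation beyond
the shared waveform (real volvel and WSS co-vary), flow-split phase lags,
and measurement/segmentation error in morphometry. Passing tests
therefore demonstrate correctness of the *computational pipeline* and
qualitative reproduction of the group structure, not clinical validity
on real CFD output.

## Statistical procedures and their conventions

- **Group screen.** Classic Levene test (absolute deviations from the
  *group mean*, not the median) gates each comparison: Levene p < 0.05
  → Welch's t-test, otherwise pooled t-test. Categorical covariates use
  the chi-square test with Yates continuity correction on 2×2 tables —
  the corrected test exactly reproduces the published clinical-table
  p-values (0.653 for sex, 0.270 for rupture status) while the
  uncorrected one does not, which settles an otherwise unstated
  convention. No multiplicity correction is applied across the 91
  features; raw p-values are reported, deliberately, and readers should
  treat the screen as descriptive.
- **Temporal descriptors.** Percentiles use linear interpolation between
  order statistics (R type 7) and `std` is the sample SD (n − 1): both
  are the dominant defaults and deterministic. The analysis window
  defaults to the **second cardiac cycle only** — dropping the first
  computed cycle is standard practice against initialization transients
  — and is configurable to the full two-cycle record (`window = "full"`
  or a numeric interval), since the source description is ambiguous on
  this point.
- **Univariate predictors.** AUROC is the Mann-Whitney concordance with
  tie correction; features are kept in raw orientation (an AUROC of 0.22
  is reported as 0.22, never flipped). AUPRC is the area under the
  precision-recall *step* curve without interpolation. The operating
  point maximizes Youden's J with ties broken toward higher specificity.
  Confidence intervals are stratified percentile bootstrap (resampling
  within class, default 2000 resamples, seeded); paired AUROC
  differences use DeLong's test (the standard same-subject choice; a
  bootstrap alternative can be built from `bootstrap_ci()`).
- **Multivariate model.** The pipeline order is fixed: standardize
  (mean 0, SD 1) → univariate logistic screen (Wald p < 0.05; completely
  separated features are excluded with a warning because their Wald p is
  meaningless) → iterative VIF filter (VIF = 1/(1 − R²), computed as the
  diagonal of the inverse correlation matrix with a regression fallback
  near singularity; remove the largest until all ≤ 10) → SMOTE
  oversampling of the recanalized class to parity (k = 5 neighbors,
  capped at minority size − 1; synthetic patients are convex
  combinations of real minority neighbors; seeded) → **backward**
  stepwise elimination by Wald p until all retained features have
  p < 0.05 (backward is the natural reading of starting from all
  multicollinearity survivors; an empty model is a valid outcome) →
  Hosmer-Lemeshow deciles-of-risk test (quantile bins, merged when
  degenerate, df = bins − 2) → ROC/PRC evaluation.
- **Coefficient intervals.** Reported bounds are the 5th and 95th
  percentiles of the Wald interval (a 90% interval), matching the
  "5% CI / 95% CI" table rendering; `ci_level` switches to a
  conventional 95% interval if preferred.
- **Evaluation protocol.** The default is resubstitution on the
  SMOTE-balanced set, mirroring the reference analysis; this is
  *optimistic* (synthetic minority points resemble their parents), which
  is why `eval = "cv"` adds a stratified 5-fold cross-validated AUROC
  and the log records the protocol used.
- **SMOTE placement.** Balancing is applied after the screen and VIF
  filter and before the multivariate fit, following the order in which
  the reference analysis describes its steps; the stage functions are
  exported, so other placements can be composed explicitly.

## Verification design and problem sizes

Each metric has an independent brute-force oracle in the test suite
(pairwise concordance for AUROC, naive threshold sweeps for AUPRC and
the Youden cutoff, normal-equation least squares for VIF, manual binning
for Hosmer-Lemeshow, first-principles ANOVA on absolute deviations for
Levene), checked over hundreds of random small instances; DeLong is
cross-checked against an independent reference implementation.
Statistical calibration is tested at the study's imbalance (57/9):
univariate-screen type-I error over 500 null cohorts against binomial
99% bounds of 0.05, and bootstrap CI coverage of a known AUROC of 0.7
over 500 replicates against the nominal 95% within a five-point band
(percentile intervals with nine positives are expected to sit slightly
below nominal). Selection behavior is tested by planting a 3-feature
logistic signal (coefficients 0.8, 0.6, −0.7) among four noise features
at n = 1000: "recovery" means all three true features are retained with
estimates within 3 SE of truth — exact-support recovery is the wrong
yardstick for α = 0.05 backward elimination, which by construction
admits each noise feature with ~5% probability. Qualitative
reproduction uses 200 cohorts at the default effect structure with
coarser fields (25 spatial samples, 0.02 s sampling) to keep the suite
fast: the PD-average family must outrank the volvel, WSS and P families
in median AUROC rank, and the multivariate model must beat the best
univariate predictor in most replicates.

## Limitations

Synthetic cohorts validate code, not clinical claims. The generator's
independence assumptions make multicollinearity milder than in real
feature sets (where the 14 descriptors of one parameter are strongly
correlated); resubstitution-with-SMOTE performance numbers are upper
bounds; and absolute performance values on synthetic cohorts depend on
the assumed effect sizes, so only their qualitative ordering is asserted
anywhere. Handling of real CFD output requires only that fields be
provided as spatial-sample-by-time matrices with area weights — mesh
I/O is out of scope.
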