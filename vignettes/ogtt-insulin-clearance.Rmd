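---
title: "Methods: OGTT insulin secretion, clearance and sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OGTT insulin secretion, clearance and sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogttclear)
```

`ogttclear` derives the determinants of hyperinsulinemia — insulin
secretion, clearance and sensitivity — from a 3-hour oral glucose
tolerance test (OGTT) sampled at 0, 10, 20, 30, 60, 90, 120, 150 and
180 minutes, and relates them to obstructive sleep apnea (OSA) severity
graded from the apnea–hypopnea index (AHI). This vignette documents the
models, the tunable parameters, the numerical choices, and what the
bundled synthetic-cohort generator does and does not emulate.

## The C-peptide kinetic model

C-peptide is co-secreted with insulin in equimolar amounts but, unlike
insulin, is not extracted by the liver, so its plasma concentration
reflects pancreatic secretion filtered only by well-characterized
peripheral kinetics. We model those kinetics with the standard
two-compartment description, whose plasma impulse response is
biexponential:

$$h(t) = \frac{1}{V_d}\left[f\,e^{-k_1 t} + (1-f)\,e^{-k_2 t}\right],
\qquad k_i = \ln 2 / t_{1/2,i},$$

with fast fraction $f$, half-lives $t_{1/2,1} < t_{1/2,2}$ (minutes) and
distribution volume $V_d$ (litres). Plasma C-peptide is then

$$C(t) = c_0\,D(t) + \int_0^t h(t-s)\,\mathrm{ISR}_{abs}(s)\,ds,$$

where $\mathrm{ISR}_{abs} = \mathrm{ISR}\cdot\mathrm{BSA}$ converts the
per-body-surface-area secretion rate (pmol min⁻¹ m⁻²) to pmol/min and
$D(t)$ is the washout of the fasting pool. We assume the subject is at
steady state at $t = 0$ (secretion constant before the load), which ties
the fasting secretion rate to the fasting concentration:
$\mathrm{ISR}_\mathrm{fast} = c_0 \cdot \mathrm{MCR} / \mathrm{BSA}$ with
$\mathrm{MCR} = V_d / [f/k_1 + (1-f)/k_2]$. This is the standard
assumption for OGTT deconvolution; without it the early secretion is not
identifiable.

Kinetic parameters are not estimated per subject (that would require a
bolus-injection study); they come from a population standardization of
the Van Cauter type, keyed by clinical status (`normal`, `obese`,
`diabetic`) and scaled to the subject's body-surface area. The table
ships as a versioned YAML file
(`system.file("extdata", "cpeptide_kinetics.yaml", package = "ogttclear")`)
rather than being hard-coded, so it can be audited and swapped; every run
log records its content hash. For this package's target population —
non-diabetic children and adolescents with obesity — the `obese` block is
the default; the choice is exposed because the appropriate class for such
cohorts is genuinely debatable. BSA uses the Mosteller formula
$\sqrt{wh/3600}$ by default (Du Bois and Haycock are selectable), a
common choice in paediatrics.

ISR is represented as a piecewise-constant function on a 5-minute
subgrid (36 segments on [0, 180]). This makes the forward convolution a
finite sum of exact exponential integrals — no quadrature error — and
the inverse problem finite-dimensional.

## Deconvolution

With 9 samples and 36 unknown segments the inversion is ill-posed, so
`deconvolve_isr()` solves the regularized non-negative least-squares
problem

$$\min_{x \ge 0}\; \sum_t \big(C_\mathrm{model}(t) - C_\mathrm{obs}(t)\big)^2
 + \lambda \sum_j \big(\Delta^2 x\big)_j^2,$$

where $\Delta^2$ takes second differences of the secretion profile
*including* the fasting segment pinned by $C(0)$, so the estimate departs
smoothly from the fasting rate. Design choices, in order of consequence:

- **Curvature penalty, not first differences.** Secretion during an OGTT
  is smooth at this sampling density; pulsatility is unidentifiable from
  9 samples, and a first-difference penalty would bias the profile toward
  a staircase.
- **Non-negativity as a hard constraint.** The active-set
  (Lawson–Hanson) solver enforces $x \ge 0$ exactly; negative rates are
  physically meaningless and clipping after the fact would bias the AUC.
  The solver is deterministic with no random initialization.
- **$\lambda$ by generalized cross-validation.** GCV is evaluated over
  21 log-spaced multiples ($10^{-3}$–$10^{3}$) of a data-scaled reference
  weight (the ratio of squared Frobenius norms of the design and penalty
  blocks). GCV uses the linear ridge smoother, where its
  effective-degrees-of-freedom form is exact; the constraint is then
  imposed by a single NNLS solve at the selected weight. Exact ties
  resolve toward the larger (smoother) $\lambda$. The per-subject
  selected weight is recorded in the run log.
- **Degenerate inputs.** All-zero C-peptide, a missing fasting sample,
  or fewer than 5 samples are hard errors; per-subject failures inside
  the cohort pipeline are quarantined with reasons rather than aborting
  the run.

Because the design matrix enters only through the subject scalar
$\mathrm{BSA}/V_d$, the ridge factorizations and degrees of freedom are
precomputed once per kinetic-parameter set and reused across subjects;
the validation studies below run ~70,000 deconvolutions this way.

## The index panel

All inputs are canonicalized to glucose mg/dL, insulin pmol/L, C-peptide
pmol/L (1 µU/mL = 6.0 pmol/L, 1 mmol/L glucose = 18.0 mg/dL; an nmol/L
tag is supported for C-peptide because published tables sometimes print
nmol-scale values under a pmol/L heading, and fasting C-peptide below 30
pmol/L triggers a unit-suspicion warning rather than a silent rescale).

- **HOMA-IR** $= G_0 I_0 / 405$, insulin in µU/mL.
- **Matsuda index (WBISI)**
  $= 10^4/\sqrt{G_0 I_0 \bar G \bar I}$ with time-weighted means by
  trapezoid. The mean window defaults to 0–120 min — the index's classic
  formulation — even though sampling extends to 180 min; the window is a
  config option because either convention appears in practice.
- **HIRI** $= \mathrm{AUC}_G^{0\text{–}30}\times
  \mathrm{AUC}_I^{0\text{–}30}$, the early hepatic response to the load.
  It is reported in raw product units; group contrasts of HIRI are
  rank-based, so the scale is immaterial.
- **Insulin clearance**: fasting
  $CL_0 = \mathrm{ISR}_\mathrm{fast}/I_0$ and post-load
  $CL_{180} = \mathrm{AUC}_\mathrm{ISR}/\mathrm{AUC}_I$ over the full
  3 hours, both in L min⁻¹ m⁻². These are ratio estimators, not
  compartmental parameters: they quantify how much circulating insulin a
  unit of secretion sustains.
- **Beta-cell glucose sensitivity**: the least-squares slope of ISR
  against glucose (mmol/L) interpolated to the segment midpoints, in
  pmol min⁻¹ m⁻² mM⁻¹, with its $R^2$. This is the dose–response slope
  only; the rate-sensitivity and potentiation components of full
  beta-cell models are deliberately out of scope, and outputs are
  labelled as the slope surrogate.
- **Stumvoll MCR** $= 18.8 - 0.271\,\mathrm{BMI} - 0.0052\,I_{120} -
  0.27\,G_{90}$ (mL min⁻¹ kg⁻¹), chosen among the Stumvoll variants
  because its units match clinical reporting practice.
- **OSA grading**: AHI ≤ 1 none, (1, 5] mild, (5, 10) moderate, ≥ 10
  severe; moderate and severe merge into one analysis group, matching
  the two-group contrast the statistics layer performs.

## Statistics layer

Cohort contrasts follow small-sample clinical practice: a
Lilliefors-corrected Kolmogorov–Smirnov screen (estimated-parameter
critical values — the plain KS test with estimated mean and SD would be
anti-conservative) routes each variable to Student's t-test
(mean ± SD) or Mann–Whitney (median, IQR). Mann–Whitney is exact for
group sizes ≤ 20 without ties, otherwise a normal approximation with
continuity correction. Categorical variables use Fisher's exact test
when any expected cell is below 5, chi-square otherwise. OGTT curves are
compared point by point with Mann–Whitney. No multiplicity adjustment is
applied to the primary p-values — mirroring descriptive cohort-table
practice — but every table reports the number of tests and a
Benjamini–Hochberg column so readers can judge for themselves. Spearman
correlations (average ranks for ties, t-approximation p-values) relate
AHI to the derived indices.

## The synthetic cohort generator

No public dataset pairs paediatric polygraphy with 3-h OGTT C-peptide
series, so validation uses a generator with known ground truth
(`simulate_cohort()`). Its defaults describe the study conditions the
package targets: 36 mild plus 34 moderate–severe OSA subjects, AHI drawn
log-uniform within (1, 5] and (5, 25] (AHI is right-skewed), and OGTT
curves built as follows:

- **Glucose**: a template excursion (baseline 66 mg/dL, peak
  136 mg/dL at 35 min, post-peak exponential return at 0.006 min⁻¹)
  with smooth between-subject variation and 2% assay noise. The low
  fasting baseline mirrors reported paediatric obesity cohorts.
- **Secretion**: ISR$(t) = $ basal $+$ slope $\cdot (G(t)-G_0)/18$,
  basal 100 pmol min⁻¹ m⁻², slope 140 pmol min⁻¹ m⁻² mM⁻¹, 25%
  between-subject CV — a pure dose–response beta-cell with no
  AHI coupling.
- **C-peptide**: the exact forward convolution of the true ISR, plus 4%
  multiplicative assay noise (a typical immunoassay CV).
- **Insulin**: a single post-hepatic pool
  $dI/dt = f_{ph}\,\mathrm{ISR}_{abs}/V - k\,I$ with hepatic first-pass
  survival $f_{ph} = 0.5$ (the liver extracts roughly half of endogenous
  insulin on first pass) and subject-specific clearance
  $CL = CL_\mathrm{ref}\,e^{\beta \log(1+\mathrm{AHI})}\cdot
  \varepsilon_i$, $CL_\mathrm{ref} = 1.15$ L min⁻¹ m⁻², 25% CV. The
  first-pass fraction is absorbed into the clearance scale, so the
  recorded "true" clearance is exactly the quantity the pipeline's
  $CL_{180}$ ratio estimates; `ahi_effect_for_deficit(0.2)` returns the
  $\beta$ giving a 20% median clearance deficit between the default AHI
  ranges (−0.168, the generator default).

These defaults were chosen once for internal consistency with published
paediatric-obesity OGTT tables (fasting insulin ≈ 90 pmol/L, basal
clearance ≈ 1.15 L min⁻¹ m⁻², HOMA-IR ≈ 2.5, Matsuda ≈ 3.5–4). One
tension is worth recording: published tables that print a time-averaged
total ISR near 80 pmol min⁻¹ m⁻² alongside a glucose sensitivity near
130 pmol min⁻¹ m⁻² mM⁻¹ are not jointly reproducible under realistic
glucose excursions (a 2–3 mM mean excursion at that slope forces a much
larger mean ISR); the generator keeps the fasting rows and the slope
consistent and lets total ISR fall where the dose–response model puts
it.

The only AHI coupling in the generator is through clearance: higher AHI
lowers clearance, which raises insulin levels and therefore HIRI while
leaving secretion untouched. That is precisely the causal structure the
pipeline is meant to detect, which makes the generator a fair test of
*detection* but not of *discrimination* against rival mechanisms. Other
things real data have that the generator does not: glucose–insulin
feedback (curves are template-driven, not a closed-loop physiologic
model), secretion pulsatility, incretin-phase asymmetries, assay drift,
and missing samples. Passing the validation suite therefore shows the
estimator chain is correct and well-calibrated under the stated
mechanism, not that the mechanism is true of any particular cohort.

All randomness flows from one master seed through named substreams
(anthropometry, AHI, curves, noise), so scenarios that differ in one
component keep every other draw identical — used, for example, to verify
that switching the AHI effect off changes clearance but not
anthropometry.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:
a noiseless deconvolution round trip (relative RMSE of the recovered
profile over [10, 180] min); the forward model's closed-form steady
state; hand-evaluated oracle values for every scalar index; per-subject
clearance recovery on one 70-subject cohort (noiseless and with assay
noise); detection of the 20% clearance deficit over 100 replicate
cohorts; null calibration (AHI effect switched off) of the group test
and the Spearman test — 1000 replicates in the test suite, 400 in the
acceptance script; and exact-enumeration oracles for Mann–Whitney
(group sizes ≤ 8), Fisher's test and the OSA grading partition. These
sizes were chosen so the whole suite completes in minutes on a single
core while keeping Monte-Carlo error well below the tolerances being
asserted.

## Known limitations

- Kinetic parameters are population values; true per-subject kinetics
  deviate, and that deviation propagates into ISR and clearance levels
  (though not their ranks, which is what the statistics layer uses).
- The steady-state-at-baseline assumption fails for subjects not
  actually fasting at $t = 0$.
- $CL_{180}$ inherits a small positive bias from the non-zero net change
  in the insulin pool over the window and from trapezoidal integration
  on the sparse late grid; the recovery study quantifies it (median
  relative error well under 10%).
- The glucose-sensitivity slope is a surrogate for full beta-cell
  dose–response modelling and ignores hysteresis; when secretion lags
  glucose the slope mixes dose–response with potentiation.
- The statistics layer implements the descriptive two-group design it
  mirrors; it deliberately offers no adjusted or regression modelling.
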