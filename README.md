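# ogttclear

Insulin secretion, clearance and sensitivity from the 3-hour oral
glucose tolerance test (OGTT), with obstructive sleep apnea (OSA)
phenotyping for paediatric obesity cohorts.

Hyperinsulinemia in children with obesity and OSA can arise from three
mechanisms — more secretion, less whole-body sensitivity, or less
clearance of insulin from the circulation. Telling them apart requires
estimating the insulin secretion rate (ISR) independently of plasma
insulin. `ogttclear` does this by **C-peptide deconvolution**: C-peptide
is co-secreted with insulin 1:1 but not extracted by the liver, so
inverting its two-compartment kinetics

$$C(t) = c_0\,D(t) + \int_0^t h(t-s)\,\mathrm{ISR}_{abs}(s)\,ds,
\qquad h(t) = \tfrac{1}{V_d}\big[f e^{-k_1 t} + (1-f)e^{-k_2 t}\big]$$

recovers ISR(t). The inversion is a regularized non-negative
least-squares problem (curvature penalty, weight chosen by generalized
cross-validation, fasting steady state anchored to C(0)) on a 5-minute
piecewise-constant grid, with Van Cauter-type population kinetics
standardized to body-surface area and clinical status.

From the recovered secretion profile and the measured curves the package
derives the full index panel used in clinical OGTT phenotyping:

| Index | Definition | Units |
|---|---|---|
| CL₀ | fasting ISR / fasting insulin | L min⁻¹ m⁻² |
| CL₁₈₀ | AUC(ISR) / AUC(insulin) over 0–180 min | L min⁻¹ m⁻² |
| HIRI | AUC₀₋₃₀(glucose) × AUC₀₋₃₀(insulin) | product units |
| Matsuda (WBISI) | 10⁴/√(G₀I₀·Ḡ·Ī), means over 0–120 min | — |
| HOMA-IR | G₀·I₀/405 (insulin µU/mL) | — |
| Stumvoll MCR | 18.8 − 0.271·BMI − 0.0052·I₁₂₀ − 0.27·G₉₀ | mL min⁻¹ kg⁻¹ |
| Glucose sensitivity | slope of ISR vs glucose (dose–response) | pmol min⁻¹ m⁻² mM⁻¹ |

OSA severity is graded from the apnea–hypopnea index (AHI ≤ 1 none;
(1, 5] mild; (5, 10) moderate; ≥ 10 severe; moderate+severe pooled for
analysis), and a statistics layer reproduces the standard small-cohort
design: KS/Lilliefors-screened t-test or Mann–Whitney group contrasts,
Fisher/chi-square for categoricals, point-by-point curve comparison, and
Spearman correlations of every index with AHI.

Because paired polygraphy + OGTT C-peptide datasets are not publicly
available, the package ships a synthetic-cohort generator
(`simulate_cohort()`) with known ground truth — AHI-coupled insulin
clearance, AHI-independent beta-cell — used by the test suite for
round-trip, recovery, power and calibration studies. See the methods
vignette (`vignettes/ogtt-insulin-clearance.Rmd`) for every modelling
choice.

## Worked example

```r
library(ogttclear)

res <- run_pipeline(run_config(simulate = sim_config(seed = 1)))
subset(res$stats$group_table,
       variable %in% c("cl_total", "hiri", "matsuda_wbisi"),
       c(variable, test, summary_mild, summary_modsev, p))
#>       variable         test        summary_mild      summary_modsev           p
#>  matsuda_wbisi       t_test         3.25 ± 1.02        2.61 ± 0.729 0.003125734
#>           hiri       t_test 1.86e+07 ± 5.29e+06 2.26e+07 ± 6.95e+06 0.008602960
#>       cl_total mann_whitney  0.962 (0.845-1.07) 0.832 (0.641-0.943) 0.002384664

res$stats$corr_table
#>      index spearman_r            p  n note
#>   cl_basal -0.4206281 0.0002882916 70
#>   cl_total -0.3995626 0.0006109423 70
#>       hiri  0.2407663 0.0446682187 70
#>  total_isr -0.1126936 0.3529676480 70
```

The simulated cohort (36 mild, 34 moderate–severe OSA) embeds a ~20%
median clearance deficit in the moderate–severe group and no effect on
secretion. The pipeline recovers exactly that structure: post-load
clearance CL₁₈₀ is lower in moderate–severe OSA (0.83 vs 0.96
L min⁻¹ m⁻², Mann–Whitney p = 0.002), HIRI is higher (p = 0.009), AHI
correlates negatively with both clearance measures (ρ ≈ −0.40) and
positively with HIRI (ρ = 0.24), while total ISR shows no association
(p = 0.35) — lower clearance, not more secretion, drives the simulated
hyperinsulinemia. With an output directory
(`run_config(..., outdir = "out")`) the same call writes the per-subject
index table, the three report tables, tidy ISR profiles and a JSON run
log (config hash, seed, per-subject regularization weights).

To analyze your own data, write it as wide CSV (`g0,g10,...,i0,...,c0,...`
plus demographics and `ahi`) or long CSV and describe the layout and
units with `cohort_schema()`; see `?read_cohort`.

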