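# vitdmr

Linear and non-linear Mendelian randomization (MR) of serum
25-hydroxyvitamin D (25(OH)D) and adolescent suicidality, at the
individual level.

## What this is for

Observational studies link low vitamin D status to suicidal ideation (SI),
plans (SP) and attempts (SA) in adolescents, but cannot separate causation
from confounding. `vitdmr` implements the full causal-inference pipeline
for a three-wave cohort with genotype data:

* an **unweighted vitamin D polygenic score** (count of 25(OH)D-lowering
  alleles at rs10741657, rs4588, rs7041) as the genetic instrument, with
  SNP screening, strength and pleiotropy diagnostics — instrument strength
  is `F = (N − 2) R² / (1 − R²)`, with `F > 10` the conventional adequacy
  bound;
* **observational models**: adjusted logistic regressions for the
  continuous exposure (OR per ng/mL) and for the clinical categories
  (deficiency < 20, insufficiency 20–<30, sufficiency ≥ 30 ng/mL), plus a
  Royston–Altman fractional-polynomial (FP) non-linearity test;
* **linear MR** by the ratio-of-coefficients method,
  `β̂_IV = β̂_GY / β̂_GX`, with first-order Taylor confidence intervals
  and a closed-form power calculation for binary outcomes;
* **non-linear MR** by decile-stratified localized average causal effects
  (LACE): the exposure is residualized on the instrument, the sample split
  into 10 quantiles of the instrument-free exposure, a ratio estimate
  fitted per stratum, and an FP meta-regression of the LACEs run against
  the stratum mean exposure, reporting the fractional polynomial,
  quadratic and Cochran's Q non-linearity tests plus instrument-constancy
  diagnostics;
* **sex-stratified** variants of every stage, and a config-driven
  `run_all()` that writes the result tables as TSV with a JSON manifest;
* a seeded **synthetic-cohort generator** reproducing the statistical
  structure such cohorts report (exposure mean 23.12, SD 5.76 ng/mL;
  baseline SI/SP/SA prevalences 24.1%/10.1%/1.5%; calibrated instrument
  R² of 3.97%; configurable null/linear/threshold causal effects), so the
  whole pipeline is testable without restricted data.

It is aimed at epidemiologists and biostatisticians running individual-level
MR on modest cohorts, and at methods work that needs a calibrated test bed
for stratified non-linear MR.

## Worked example

```r
library(vitdmr)

cohort <- generate_cohort(generator_config(seed = 42))  # null causal model
fit_instrument(cohort)
#> Instrument-exposure association (25(OH)D ~ PGS, adjusted):
#>   beta = -1.052 (SE 0.134), p = 7.13e-15
#>   R^2 = 0.0417, F = 61.98, n = 1426

ratio_mr(cohort, "si", "baseline")
#> Linear MR (ratio of coefficients): SI, baseline
#>   n = 1426 (358 cases); instrument F = 61.98
#>   OR per ng/mL = 1.054 (95% CI 0.953-1.165), P_linear = 0.309

nonlinear_mr(cohort, "si", "incident_1y")
#> Non-linear MR over 10 of 10 strata
#>   pooled LACE = 0.0306 (SE 0.0753) log-odds per ng/mL
#>   P_fp = 0.640, P_quadratic = 0.518, P_CochranQ = 0.369
#>   instrument constancy: P_Q = 0.012, P_trend = 0.105

mr_power_binary(1411, 0.0397, 0.241, true_or = 1.5)
#> MR power (binary outcome): n = 1411, R^2 = 0.040, K = 0.241,
#>   OR = 1.50/SD -> power = 0.255 at alpha = 0.05
```

Reading the output: the first-stage coefficient is negative because the
score counts 25(OH)D-*lowering* alleles; `F = 61.98` clears the strength
bound, so the ratio is taken. Under the generator's null causal model the
MR odds ratio per ng/mL is compatible with 1 and all three non-linearity
tests are non-significant, as they should be. The power line says a true
odds ratio of 1.5 per SD of 25(OH)D would be detected about a quarter of
the time at this sample size and instrument strength — individual-level MR
at n ≈ 1400 is informative only about fairly large effects.

The whole analysis can also be driven end to end:

```r
res <- run_all(cohort, analysis_config(stratify_sex = TRUE), out_dir = "out")
res$table4   # MR odds ratios and the three non-linearity p-values
```

or from a shell via `inst/scripts/vitdmr-cli.R`
(`simulate` / `validate` / `run` subcommands).

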