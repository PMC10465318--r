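---
title: "Methods: polygenic-score MR of serum 25(OH)D and adolescent suicidality"
author: "vitdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic-score MR of serum 25(OH)D and adolescent suicidality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Low serum 25-hydroxyvitamin D (25(OH)D) has been associated with suicidal
ideation (SI), plans (SP) and attempts (SA) in adolescents, but
observational associations are vulnerable to confounding and reverse
causation. `vitdmr` implements an individual-level Mendelian randomization
(MR) pipeline that uses an unweighted vitamin D polygenic score as the
genetic instrument, alongside the traditional observational analysis, for
dichotomous suicidality outcomes measured at three annual waves. Because
the kind of cohort this targets is typically not publicly deposited, the
package also ships a seeded synthetic-cohort generator that reproduces the
statistical structure the analysis assumes; every stage of the pipeline is
calibrated against it in the test suite.

## The instrument

The score counts 25(OH)D-*lowering* alleles at three SNPs in vitamin D
synthesis/metabolism genes (CYP2R1 rs10741657, GC rs4588 and rs7041), so a
higher score means genetically lower 25(OH)D and the first-stage
coefficient is negative by construction. Candidate SNPs whose adjusted
association with 25(OH)D does not reach the screening level (default
$\alpha = .05$, the same two-sided level used throughout) are excluded by
`screen_snps()`; monomorphic SNPs are excluded with an explicit reason
rather than an error.

Instrument strength is summarised by the incremental $R^2$ of the score
after age and sex in a linear model for 25(OH)D, converted to
$$F = \frac{(N-2)\,R^2}{1-R^2},$$
the one-regressor F form; $F > 10$ is the conventional adequacy bound and
`ratio_mr()` refuses to divide below it unless forced. We report the
*partial* (incremental) $R^2$ — the share of the covariate-adjusted
residual variance explained by the score — because the instrument model is
itself adjusted for age and sex. `check_pleiotropy()` probes the exclusion
restriction descriptively: linear-model slopes for continuous risk factors,
(multinomial) logistic likelihood-ratio tests for categorical ones.

## Observational models

`build_outcomes()` constructs, per trait, a baseline outcome (the wave-1
report) and incident outcomes restricted to participants negative for
*that trait* at wave 1: 1-year incidence is the wave-2 report, 2-year
incidence is positivity at wave 2 and/or wave 3 (a participant positive at
wave 2 with wave 3 missing is still a case; a participant negative at wave
2 with wave 3 missing is dropped and counted). The per-trait restriction —
rather than requiring negativity on all three traits — matches the
denominators such cohorts report.

25(OH)D enters either continuously (odds ratio per ng/mL from a
maximum-likelihood logistic fit, Wald p) or in the standard clinical
categories (deficiency < 20, insufficiency 20–<30, sufficiency ≥ 30 ng/mL,
boundaries belonging to the higher category, deficiency as reference).
All observational models adjust for the full covariate set (sex, age,
household registration, family economy, parental education, physical
activity, impulsivity, depression, anxiety); complete cases per model; no
multiple-testing correction, mirroring the single-significance-level
convention of this literature.

Non-linearity is tested with Royston–Altman fractional polynomials (FP):
powers $\{-2,-1,-0.5,0,0.5,1,2,3\}$ with $0 \equiv \log x$ and a repeated
power $p$ contributing $x^p$ and $x^p\log x$. The exposure is divided by 10
before transforming, purely to keep $x^3$ numerically tame; the FP basis is
invariant to this rescaling so no p-value changes. `fp_nonlinearity_test()`
selects the best degree-1 and degree-2 models by deviance and reports
$P_{overall}$ (best degree-2 vs covariates-only null, 4 df) and
$P_{non\text{-}linear}$ (best degree-2 vs linear, 3 df) — the standard FP
testing convention in which the searched powers count as parameters. The
convention is known to be conservative: because the best power set is
selected before the chi-square comparison and often coincides with the
linear model, the realised type-I rate of $P_{non\text{-}linear}$ sits at
or below the nominal level (the acceptance suite measures it under a truly
linear logit at $n = 3000$).

## Linear MR

With the score $G$, exposure $X$ and outcome $Y$, the ratio-of-coefficients
(Wald) estimator combines the first-stage linear fit
$\hat\beta_{GX}$ and the logistic reduced form $\hat\beta_{GY}$, both
adjusted for age and sex only (the MR adjustment set):
$$\hat\beta_{IV} = \hat\beta_{GY}/\hat\beta_{GX}, \qquad
  \widehat{SE}(\hat\beta_{IV}) = SE(\hat\beta_{GY})/|\hat\beta_{GX}|$$
(first-order Taylor; the second-order term
$\hat\beta_{GY}^2 SE^2(\hat\beta_{GX})/\hat\beta_{GX}^4$ is available via
`second_order = TRUE` but off by default). Confidence intervals use the
fixed 1.96 multiplier; p-values are Wald z — at $n$ in the thousands the
z/t distinction is immaterial. The reduced-form log-odds coefficient is a
population log-OR; no non-collapsibility correction is attempted. Because
the instrument is a single score, no SNP-level meta-analysis is needed.

Statistical power for a binary outcome uses the closed-form normal
approximation: for a causal odds ratio $OR$ per SD of the exposure, case
fraction $K$ and instrument $R^2_{GX}$, the reduced-form Wald statistic is
approximately $z = |\log OR|\sqrt{n R^2_{GX} K(1-K)}$ and
$power = \Phi(z - z_{1-\alpha/2}) + \Phi(-z - z_{1-\alpha/2})$. The test
suite checks this against Monte-Carlo power from the generator.

## Non-linear MR

`nonlinear_mr()` follows the localized-average-causal-effect (LACE)
design: the exposure is residualized on the instrument
(`instrument_free_exposure()`; age and sex are additionally included by
default to match the MR adjustment set, with the score-only behaviour
available), the sample is split into $K = 10$ quantile strata of the
residual (rank-based, stable ties, sizes differing by at most one), and a
ratio estimate is computed within each stratum. The stratum-specific
first-stage coefficient is used in each ratio (the full-sample option
exists) because the instrument-constancy diagnostics examine exactly those
per-stratum associations: Cochran's Q over $\hat\beta_{GX,j}$ and an
inverse-variance weighted trend of $\hat\beta_{GX,j}$ on the stratum mean
exposure.

The meta-regression treats $LACE_j$ as the derivative $h'(\bar x_j)$ of a
fractional-polynomial effect function $h(x)=\sum_k \beta_k x^{p_k}$
evaluated at the stratum mean, fitted by inverse-variance weighted least
squares over the same FP grid (degrees 1 and 2). A linear causal effect
has constant derivative, so the linear reference model is the weighted mean
of the LACEs. Three tests are reported:

* **fractional polynomial test** — chi-square difference of weighted RSS
  between the best degree-1 FP and the linear model, 1 df (the searched
  power is the extra parameter);
* **quadratic test** — Wald p on the slope of the weighted regression of
  $LACE_j$ on $\bar x_j$ (fixed-effect convention: coefficient covariance
  $(X'WX)^{-1}$, no residual rescaling);
* **Cochran's Q** — heterogeneity of the LACEs about their pooled mean,
  chi-square with $K-1$ df.

Strata with a single outcome class, separation, or a degenerate
within-stratum first stage are flagged and excluded, with $K$ reduced
accordingly; all flags surface in the strata diagnostics table.

As with the observational FP test, the best-power search makes the
fractional polynomial test conservative: under the causal null its
realised rejection rate at the .05 level is about 0.01–0.02 in the
package's own calibration runs, while the quadratic and Cochran's Q tests
calibrate at the nominal rate. We keep the 1-df convention because it is
the standard parameter-difference accounting for this family; the
conservatism is a property of the test, not a defect of the
implementation, and is visible in the acceptance suite.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, with
defaults fixed at the study conditions: $n = 1426$; 60.8% male; age
$\mathcal N(12.48, 0.48^2)$; 25(OH)D marginally $\approx \mathcal
N(23.12, 5.76^2)$ ng/mL; baseline SI/SP/SA prevalences 24.1%/10.1%/1.5%;
1-year incident rates 12.8%/7.8%/2.8% and 2-year rates 25.6%/13.4%/4.1%
among per-trait baseline negatives. Genotypes are drawn binomially at
Hardy–Weinberg proportions with lowering-allele frequencies 0.60/0.30/0.25
— documented placeholders plausible for an East-Asian population, chosen
once as configuration values, not estimates. The per-allele effect is
negative (lowering-allele convention; a positive printed first-stage
coefficient under the opposite coding is treated as a coding artefact) with
magnitude calibrated analytically so the score explains 3.97% of the
exposure variance: $|\beta| = \sigma_X\sqrt{R^2/V_G}$ with
$V_G = \sum_k 2p_k(1-p_k)$.

A single standard-normal latent confounder shifts the exposure (default
−1.0 ng/mL per SD) and every outcome's log-odds (default +0.3 per SD) —
values picked once to represent modest shared confounding of roughly the
size adjustment covariates absorb in such cohorts. Gaussian exposure noise
is scaled so the marginal SD is exactly the configured 5.76 ng/mL. The
causal effect of the exposure on each outcome's log-odds is configurable:
`null` (the default, matching the all-null MR finding this design
emulates), `linear` (a constant slope in log-odds per ng/mL), or
`threshold` (a slope below a cut-point, flat above — the
deficiency-harm hypothesis). Wave-1 intercepts are solved by `uniroot` so
the realised prevalence matches the target in expectation; wave-2 and
wave-3 intercepts are solved among the per-trait at-risk subsets so the
configured incident rates hold among baseline negatives. Baseline-positive
trajectories use a simple persistence probability (0.6) that no incident
analysis touches. Missingness, when requested, is completely at random,
matching the complete-case analyses downstream.

Each column family draws from its own seeded RNG substream, so the tables
are reproducible byte-for-byte and adding a generated column leaves earlier
columns unchanged.

What the generator does **not** emulate: linkage disequilibrium between the
three SNPs, genotyping error, population stratification, any joint
covariate structure beyond marginals, non-random missingness, and
season/assay effects on 25(OH)D. Calibration results on synthetic cohorts
therefore demonstrate the estimators' statistical behaviour under the
assumed model, not robustness to those real-data complications.

## Numerical choices and problem sizes

* FP transforms operate on exposure/10; all bases are scale-invariant.
* Logistic fits flag perfect separation (fitted probabilities at machine
  bounds together with |coefficient| > 15) instead of returning divergent
  estimates.
* The ratio refuses division for $|\hat\beta_{GX}|$ below $10^{-10}$ and,
  by default, for instrument $F < 10$.
* Quantile assignment breaks ties by stable row order, making the
  stratification deterministic given the table.
* Intercept calibration solves on $[-40, 40]$ log-odds with tolerance
  $10^{-10}$; prevalence 0 or 1 short-circuits to a degenerate column.
* Calibration test sizes were chosen for stable Monte-Carlo error at
  desk scale: 200 replicates of $n = 10{,}000$ for ratio recovery and
  coverage, 1000 replicates of $n = 3000$ for the observational FP type-I
  rate, 500 replicates of $n = 2500$ for the null calibration of the three
  non-linear MR tests, and 100 replicates of $n = 20{,}000$ with threshold
  slope 0.15 log-odds per ng/mL below 20 ng/mL (chosen a priori by an
  analytic power sketch as a "strong" effect) for the quadratic test's
  power.

## Known limitations

* The FP-based tests (observational and meta-regression) are conservative,
  as discussed; a parametric bootstrap would calibrate them exactly but is
  out of scope here.
* First-order Taylor intervals understate uncertainty when the
  within-stratum first stage is weak; such strata are flagged rather than
  propagated.
* Rare outcomes (SA at 1.5% baseline prevalence) routinely produce
  single-class strata at $K = 10$ and desk-scale $n$; the pipeline reduces
  $K$ and reports the exclusions rather than merging strata, since merging
  rules are not part of the design being reproduced.
* The generator's incident-rate conditioning is exact in expectation per
  realised cohort, not per draw.
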