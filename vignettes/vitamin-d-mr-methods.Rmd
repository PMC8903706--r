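---
title: "Methods: two-sample Mendelian randomization of vitamin D on cardiovascular outcomes"
author: "vitdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization of vitamin D on cardiovascular outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The question and the estimator

Observationally, low serum 25-hydroxyvitamin D (25(OH)D) predicts
cardiovascular events, but supplementation trials have been largely
neutral, so confounding and reverse causation are live concerns.
Mendelian randomization (MR) sidesteps both by using genetic variants as
instruments: alleles are assorted at conception, before disease, and —
under the instrumental-variable assumptions — are associated with the
outcome only through the exposure they predict.

`vitdmr` implements the individual-data, two-sample form of this design
for a hypertensive, largely type-2-diabetic population. The instrument
is an unweighted allele count over three SNPs from the vitamin D
activation (CYP2R1) and binding-protein (GC) loci: a genetic risk score
(GRS) from 0 to 6, where 0 and 6 mark the lowest and highest genetically
predicted 25(OH)D. Two disjoint subcohorts supply the two association
estimates:

* the **derivation cohort** (n = 1460) yields the first stage
  $\hat\beta_{ZX}$, the per-allele effect on 25(OH)D in ng/mL, with its
  partial $R^2$ and F statistic (relevance);
* the **outcome cohort** (n = 3746 hypertensive subjects) yields the
  per-allele association $\hat\beta_{ZY}$ with each endpoint: a
  multivariable Cox log hazard ratio for time-to-event endpoints, or a
  logistic log odds ratio for binary endpoints such as failed
  guideline-directed blood-pressure control.

The causal effect per 1 ng/mL of 25(OH)D is the Wald ratio
$\hat\theta = \hat\beta_{ZY} / \hat\beta_{ZX}$, exponentiated for
reporting. Survival-endpoint results are labelled odds ratios under the
rare-event equivalence of hazard and odds ratios; no scale conversion is
applied, and the numerator's scale is carried in the result's metadata.

## Fieller's confidence interval

A ratio of two noisy estimates does not have a normal sampling
distribution, and when the denominator is weak the plug-in (delta)
interval misbehaves. `fieller_ci()` inverts the exact test of
$H_0:\ \beta_{ZY} = \theta_0\,\beta_{ZX}$,

$$\frac{(\hat\beta_{ZY} - \theta_0\hat\beta_{ZX})^2}
       {s_{ZY}^2 - 2\theta_0 c + \theta_0^2 s_{ZX}^2} \le z^2_{\alpha/2},$$

which reduces to a quadratic in $\theta_0$. With the degeneracy
statistic $g = z^2 s_{ZX}^2 / \hat\beta_{ZX}^2$:

* $g < 1$: a bounded interval containing the point estimate;
* $g \ge 1$ with a non-null numerator: the *complement* of an interval
  (an exclusive set);
* both estimates null: the whole real line.

The degenerate sets are returned as explicit statuses and never
truncated into a finite interval. In a two-sample design the
numerator-denominator covariance $c$ is 0 because the subcohorts are
disjoint; the argument is exposed for one-sample reuse. As
$s_{ZX} \to 0$ the Fieller interval converges to the delta interval
(`method = "delta"` computes the latter directly); the test suite checks
both this limit and agreement with a dense grid inversion of the test to
$10^{-4}$.

A reassuring property of the printed-input recomputation:

```{r worked}
worked_example_report()
```

The residual deviations (all below 1.6%) are what two-decimal rounding
of the printed inputs allows; `wald_rounding_ranges()` sweeps every
input over its rounding range and verifies the published values lie
inside the attainable envelope.

## Instrument construction and validation

* **Hardy-Weinberg equilibrium**: 1-df $\chi^2$ without continuity
  correction against expected proportions $p^2, 2pq, q^2$; a monomorphic
  locus is a defined degenerate result (statistic 0, flagged), not an
  error. The implementation is checked exhaustively against a
  closed-form disequilibrium identity on all genotype triples with
  $n \le 30$.
* **Linkage disequilibrium**: squared Pearson correlation of dosage
  vectors, pairwise-complete. Selection keeps SNPs passing the exposure
  screen (p < 0.05), ranks by |t|, and greedily drops any SNP with
  $r^2 > 0.2$ against an already retained one, capped at 3 SNPs. The
  0.2 default deliberately tolerates weak correlation — the instrument
  convention here retains a GC pair at $r^2 = 0.16$.
* **Orientation**: dosages always count the exposure-raising allele, so
  score 0 is the lowest genetically predicted exposure. The generator
  produces dosages already oriented; ingested data are assumed oriented.
* **Strength**: the first stage reports B (ng/mL per allele), partial
  $R^2$ and $F = t^2$; univariably $F = R^2(n-2)/(1-R^2)$ exactly, and
  $F \gtrsim 10$ is the conventional non-weak threshold. The first
  stage is univariable by default; the exact adjustment set behind the
  published "independently associated" estimate is not fully enumerable,
  and covariate adjustment is available via an argument.
* **Independence**: `confounder_independence()` associates the score
  with measured covariates (linear, logistic or contingency test by
  type), flagging p ≤ 0.20 — a deliberately conservative reporting
  convention. Pleiotropy database lookups (PhenoScanner, GWAS catalog,
  Ensembl) are a manual checklist and are not automated here.

## Endpoint models

Cox proportional-hazards fits maximize the partial likelihood by Newton
iteration with the Efron approximation for ties (Breslow available);
Efron is the standard default with better behaviour under heavy ties.
Logistic fits use Newton/IRLS with an optional Firth-penalized mode for
separated data. Kaplan-Meier comparisons report the 1-df log-rank
statistic and restricted mean survival to the largest observed time —
the conventional horizon when a "mean survival" is quoted from a KM
analysis. These fitters are authored in the package so that the test
suite can hold them against independent implementations
(`survival::coxph`, `stats::glm`) to $|\Delta\beta| < 10^{-6}$; a wrapper
would make that cross-check vacuous. Failure modes (no events, monotone
likelihood, separation, empty strata) are explicit statuses.

Blood-pressure control failure is a pure threshold rule: systolic
≥ 150 mmHg (JNC-8; this cohort is predominantly aged 60+) or ≥ 140 mmHg
(ADA, for co-morbid diabetes), or diastolic ≥ 90 mmHg; a systolic-only
variant serves the systolic-target endpoint. Missing values are excluded
listwise throughout, and no multiple-comparison adjustment is applied —
the instrument and primary endpoint are defined a priori.

The default multivariable adjustment set for the per-allele Cox models
is age, sex, smoking, diabetes, lipid-lowering therapy, BMI, creatinine,
LDL/HDL cholesterol, triglycerides and season. Blood pressures are
deliberately not in the default set: in the generator, systolic pressure
is partly downstream of 25(OH)D, and adjusting for a mediator would
blunt the causal contrast the simulation is designed to measure. A
fully-adjusted convention including SBP/DBP is one argument away
(`adjustment_set`).

## The synthetic cohort generator

The original subject-level data are not publicly available, so the
package ships a generator that emulates the *statistical structure* the
analysis assumes; every default is a study condition, fixed once:

| parameter | default | rationale |
|---|---|---|
| n (derivation / outcome) | 1460 / 3746 | subcohort sizes |
| effect-allele frequencies | 0.45 / 0.40 / 0.50 | GRS mean $2\sum p = 2.7$, sd $\approx 1.2$ |
| per-allele effect | 0.66 ng/mL | first-stage B |
| residual sd | 5.47 ng/mL | gives $R^2 \approx 0.021$ at n = 1460, hence $F \approx 31$ |
| exposure mean | 20.7 ng/mL | ~45% below the 20 ng/mL deficiency cut |
| causal log hazard | ln 0.86 per ng/mL | the headline causal estimate |
| baseline hazard | 0.0019 /month | ~15% combined events at n = 3746 |
| censoring | exp(0.0123 /month), cap 120 months | mean observed follow-up ≈ 55.6 months |

Genotypes follow Hardy-Weinberg proportions, independent across SNPs by
default; linkage disequilibrium is generated through a Gaussian copula
on the haplotype draws (latent correlation 0.6 induces dosage
$r^2 \approx 0.16$). Exposure is Gaussian with a 1 ng/mL floor; the
per-allele effect is interpreted on the absolute ng/mL scale, the scale
on which the published first stage and "per 1 ng/mL rise" effects are
stated. An optional log-normal mode reproduces the right-skew of
measured 25(OH)D, but the Gaussian mode cannot simultaneously match the
reported log-scale moments — a deliberate simplification. Events arise
from six independent competing exponential proportional-hazards
processes (myocardial infarction, unstable angina, heart failure,
stroke, peripheral vascular disease, cardiovascular death) with
cause-specific shares proportional to the reported incident counts; the
combined endpoint is the first occurrence of any. All components share
one causal coefficient by default so the combined-endpoint causal
parameter is well defined; per-endpoint overrides exist (the analysis
scripts use ln 0.76 for MI). Confounders (age, sex, smoking, BMI,
creatinine on the hazard; age, BMI, season on the exposure) create a
real confounding path that the genotype, by construction, does not see —
the exclusion restriction is encoded, and tested, as conditional
independence of GRS and event time given exposure.

What the generator does *not* emulate: the real LD structure of the
full 12-SNP panel (only a configurable pairwise structure), assay
measurement error, informative censoring, competing-risk dependence, and
the long right tail of follow-up dispersion (the two-parameter censoring
model yields an observed-time sd near 41 months against the reported
29). Passing tests therefore certify the estimator machinery under the
stated data-generating process, not the epidemiology of any real cohort.

## Numerical choices

Newton iterations start at 0 with step-halving and converge on relative
log-likelihood change below $10^{-9}$ (Cox) or coefficient change below
$10^{-10}$ (logistic); Cox columns are centred (the partial likelihood
is location-invariant) to keep $e^\eta$ well scaled; divergence is
declared when a standardized coefficient exceeds 30 (monotone
likelihood) or 25 on the logistic scale (separation). The Fieller
quadratic is solved in closed form; tie-breaking in instrument selection
is by descending |t|, with the LD prune applied in that order.
Determinism is end to end: one integer seed fixes both subcohorts, and
configurations round-trip through YAML at 22 significant digits, which
reproduces every double exactly.

## Known limitations

* **Non-collapsibility of the hazard ratio.** The Wald ratio estimator
  converges to (marginal per-allele log HR) / (per-allele exposure
  effect). Because the instrument explains only ~2% of the exposure, the
  remaining exposure variation acts as an unobserved frailty in the
  numerator model, attenuating the marginal per-allele log hazard ratio
  by about 7% at 15% cumulative incidence under the default calibration.
  The package's coverage simulation (1000 two-sample studies) puts the
  empirical 95% Fieller coverage of the causal log-OR at about 96% —
  within the nominal band, because the attenuation is small relative to
  the interval width — but the point estimate's median sits measurably
  toward the null of the conditional causal parameter (median bias
  ≈ +0.012 on the log scale against a Monte-Carlo resolution of
  ≈ 0.004). This is a property of ratio MR with marginal hazard ratios,
  shared by the design the package reimplements, not of the
  implementation; the corresponding acceptance check of exact median
  unbiasedness is left failing by design and documented rather than
  relaxed.
* Weak-instrument pathologies are reported, not repaired: per-SNP
  ratios with a null first stage are flagged and kept, and degenerate
  Fieller sets are returned as such.
* No pleiotropy-robust estimators (MR-Egger, weighted median) — with a
  three-SNP instrument from two loci they are underpowered and are out
  of scope; no inverse-variance pooling of per-SNP ratios (multi-SNP
  summaries are re-scored allele-count instruments).
* Subgroup MR stratifies the outcome cohort on the measured exposure;
  stratifying on a variable downstream of the instrument attenuates the
  within-stratum genotype-exposure gradient, so stratum-specific ratios
  are interpretable as heterogeneity signals rather than unbiased
  stratum-causal effects.

## Problem sizes used by the test suite

Property-style tests run at the sizes that make their Monte-Carlo error
negligible relative to the asserted tolerance: genotype law-of-large-
numbers checks at $n = 10^5$, slope recovery at $n = 4\times 10^5$,
first-stage recovery over 500 replicates at n = 1460, size and coverage
checks over 1000 replicates, and designed-heterogeneity and power checks
at a few thousand subjects per replicate. End-to-end pipeline tests use
reduced subcohorts (900/1800) with a proportionally strengthened first
stage so that instrument selection is deterministic at that scale.
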