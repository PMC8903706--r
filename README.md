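# vitdmr

Individual-data **two-sample Mendelian randomization** of serum
25-hydroxyvitamin D (25(OH)D) on cardiovascular outcomes in a
hypertensive, largely type-2-diabetic population — rebuilt as a tested,
reusable R pipeline over a synthetic-cohort generator.

Low vitamin D status predicts cardiovascular events observationally, but
that association is confounded (adiposity, frailty, season, reverse
causation). Mendelian randomization uses genetic variants as
instruments: a **genetic risk score (GRS)** counting exposure-raising
alleles at three SNPs from the CYP2R1 and GC loci (unweighted, range
0–6) predicts 25(OH)D but — under the instrumental-variable assumptions —
is related to outcomes only through it. With the per-allele
instrument–exposure association β̂_ZX (ng/mL per allele, from a
derivation cohort) and the per-allele instrument–outcome association
β̂_ZY (log hazard or log odds ratio, from a disjoint outcome cohort), the
causal effect per 1 ng/mL of 25(OH)D is the **Wald ratio**

    θ̂ = β̂_ZY / β̂_ZX,        OR per ng/mL = exp(θ̂),

with a 95% confidence interval from **Fieller's theorem** — the exact
confidence set for a ratio of normal estimates, which stays honest when
the denominator is noisy (the set can be finite, exclusive, or the whole
line; the degeneracy statistic g = z²·se²_ZX/β̂²_ZX governs which).

The package is intended for biostatisticians and genetic
epidemiologists who want the full pipeline — Hardy-Weinberg and linkage-
disequilibrium QC, instrument selection, first-stage strength (partial
R², F), Cox/Kaplan-Meier/logistic endpoint models, Wald/Fieller causal
estimates, per-SNP, SNP-combination, deficiency-subgroup and co-morbid
sensitivity analyses — runnable end to end without access to the
original cohort: a calibrated synthetic generator reproduces the study's
statistical structure (n = 1460 / 3746, first-stage R² ≈ 2.1%, ~15%
combined events over ~55.6 months, ~45% deficiency).

## Worked example

```r
library(vitdmr)

study <- simulate_two_sample_study(sim_config(seed = 20260928))
print(study)
#> Simulated two-sample MR study
#>   derivation n = 1460, outcome n = 3746 (seed 20260928)
#>   combined events: 575 (15.3%), mean observed follow-up 55.6 months
#>   25(OH)D < 20 ng/mL: 45.1%

dc <- study$derivation$cohort; oc <- study$outcome$cohort

fs <- first_stage_fit(dc$grs, dc$exposure_25ohd)
print(fs)
#> First stage: B = 0.705 ng/mL per allele [0.474, 0.936], R^2 = 0.0240, F = 35.8, n = 1460

cox <- fit_cox(oc$time_combined, oc$event_combined, oc$grs, term = "grs",
               covariates = oc[c("age", "male", "smoking", "bmi", "creatinine")])
grs_mr(fs, cox)
#> Wald ratio per 1 ng/mL: OR = 0.9303 [0.8316, 1.0228] (Fieller, g = 0.107)
```

The first stage recovers the calibrated per-allele effect (0.66 ng/mL)
within sampling error with instrument strength F ≈ 32; the Wald ratio
estimates the protective causal odds ratio per ng/mL of 25(OH)D (the
generator's truth is 0.86), with Fieller limits that account for the
denominator's sampling error (g ≪ 1: a proper interval). Single-study
estimates scatter around that truth — over 1000 replicated studies the
ratio's median lands near exp(-0.139) ≈ 0.87 with 96% interval coverage
(see the coverage discussion in the methods vignette).

Recomputing the published headline estimates from printed inputs alone —
per-allele HR 0.90 [0.84, 0.96] for combined events, HR 0.83
[0.73, 0.94] for myocardial infarction, first stage B 0.66 [0.51, 0.82]:

```r
worked_example_report()
#>   endpoint quantity recomputed printed rel_deviation
#> 1 combined       or  0.8524530    0.86   0.008775524
#> 2 combined   ci_low  0.7555313    0.75   0.007375015
#> 3 combined  ci_high  0.9440489    0.95   0.006264274
#> 4       mi       or  0.7540342    0.76   0.007849726
#> 5       mi   ci_low  0.6017146    0.60   0.002857651
#> 6       mi  ci_high  0.9142761    0.90   0.015862345
```

Every deviation is within what two-decimal rounding of the printed
inputs permits; `wald_rounding_ranges()` proves it by interval
arithmetic over the rounding ranges.

## Analysis workflow

Numbered drivers under `analysis/` run the study as a narrative sequence
and write their tables under `results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate_cohorts.R` | generate and export the two subcohorts (TSV, minimal VCF, YAML config) |
| `analysis/02_build_instrument.R` | 12-SNP candidate-panel screen with LD, HWE QC, selection, first stage, confounder screen |
| `analysis/03_endpoint_models.R` | per-allele Cox models, Kaplan-Meier GRS median split, blood-pressure-control and deficiency logistic models |
| `analysis/04_mendelian_randomization.R` | full `run_study()` pipeline: MR table across endpoints, per-SNP/combination, deficiency-subgroup and co-morbid sensitivity rows |
| `analysis/05_worked_examples.R` | printed-input recomputation with rounding-envelope bounds |

Each is a thin script over exported functions; `run_study()` executes
the same stages programmatically and writes a manifest (seed, config
hash, subject accounting) for reproducibility.

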