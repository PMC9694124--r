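# iidrperm

Item-level permutation analysis of speech perception under two
cochlear-implant input dynamic range settings.

## What this is for

Cochlear implants map acoustic input between two programmed levels —
T-SPL (mapped to the electrical threshold) and C-SPL (mapped to the
loud-but-comfortable level) — onto the electrical output range; the
span C-SPL − T-SPL is the instantaneous input dynamic range (IIDR).
This package re-implements, as tested and reusable code, the analysis
of a small clinical study that compared the default IIDR (25/65 dB,
width 40 dB) with a wide IIDR (25/80 dB, width 55 dB) in 11 adult
unilateral CI users split into two preference groups (preCSPL65, n = 5;
preCSPL80, n = 6). Every subject took recorded speech tests under both
settings in eight conditions: 25-word lists and 15-sentence lists
scored over 60 morphemes, in quiet and in +10 dB SNR noise, at 65 and
80 dB SPL.

The statistical core is a **Monte Carlo permutation test** on pooled
binary item outcomes. For reference side *a* and comparison side *b*,
the statistic is the mean-score difference in percentage points,
D = 100 (mean(b) − mean(a)). Each of R = 100,000 iterations draws a
pseudo-*b* of size |b| from the pooled items without replacement and
recomputes D\*; the p-value is the count of iterations with D\* ≥ D
(one-sided; |D\*| ≥ |D| two-sided) divided by R. An exact enumeration
oracle (`exact_permutation_test()`) computes the same null
distribution in closed form via hypergeometric multiplicities and
backs the Monte Carlo engine in the test suite.

Because the study's item-level data were never deposited, the package
ships a **synthetic cohort generator** (`study_preset()`,
`generate_cohort()`) calibrated to the published group-by-condition
mean scores, with a logit-normal between-subject effect. The intended
audience is anyone who wants to audit, rerun, or extend this style of
small-cohort audiological comparison with resampling statistics.

## Worked example

```r
library(iidrperm)

iidr_preset("wide")
#> IIDR setting 'wide': T-SPL/C-SPL 25/80 dB (width 55 dB)

cohort <- generate_cohort(study_preset(seed = 42))
cohort
#> Item-response cohort: 11 subjects, 16 cells/subject, 7480 item rows
#> Groups: preCSPL65 n=5, preCSPL80 n=6

cell <- pool_cell(cohort, "word", "noise", 65,
                  axis = "within_iidr", grouping = "all")
result <- mc_permutation_test(cell$a, cell$b, n_resamples = 100000, seed = 7)
result
#> Monte Carlo permutation test (greater)
#>   observed mean difference: +17.455 percentage points
#>   extreme resamples: 2 of 100,000
#>   p-value: 2e-05
```

Reading the output: across all 11 subjects the words-in-noise score at
the conversational level (65 dB SPL) was 17.5 percentage points higher
under the wide IIDR in this simulated cohort (275 pooled word items per
side), and only 2 of 100,000 without-replacement resamples produced a
mean difference at least that large — p = 2 × 10⁻⁵, echoing the
study's strongly significant words-in-noise finding.

The full 40-test comparison matrix (24 within-IIDR tests across three
groupings, 16 between-group tests at fixed IIDR) runs with
`run_study(cohort, seed = ...)` and collapses to significance flags
with `significance_pattern()`. The `analysis/` scripts are thin
narrative drivers over these functions:

```sh
Rscript analysis/01_generate_cohort.R     # simulate + write results/cohort.csv
Rscript analysis/02_run_study.R           # 40 permutation tests -> results/study_report.csv
Rscript analysis/03_significance_pattern.R
```

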