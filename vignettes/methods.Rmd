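---
title: "Methods: item-level permutation analysis of speech scores under two IIDR settings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: item-level permutation analysis of speech scores under two IIDR settings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A cochlear implant maps a window of acoustic input levels — from T-SPL,
the level mapped to the electrical threshold, up to C-SPL, the level
mapped to the loud-but-comfortable stimulation level — onto the
electrical dynamic range. The width C-SPL − T-SPL is the instantaneous
input dynamic range (IIDR). The study this package models compared two
settings in 11 adult unilateral CI users: the default IIDR (25/65 dB,
width 40 dB) and a wide IIDR (25/80 dB, width 55 dB). Subjects fell into
two preference groups by the setting they had self-selected for daily
use: preCSPL65 (n = 5) and preCSPL80 (n = 6). Every subject took
recorded word and sentence tests under both settings in eight
conditions: word/sentence material, in quiet and in speech-weighted
noise at +10 dB SNR, presented at 65 and 80 dB SPL. A word list holds
25 scored words; a sentence list holds 15 sentences scored over 60
morphemes. Scores are percent correct.

With n = 11 and unmatched clinical covariates, parametric group
comparisons are fragile; the analysis instead uses a Monte Carlo
permutation test on the item-level outcomes, and this package
re-implements that pipeline end to end.

## The permutation test

For a comparison of two conditions, the binary item outcomes of all
selected subjects are pooled per side: side *a* is the reference
(default IIDR, or the preCSPL65 group), side *b* the comparison (wide
IIDR, or preCSPL80). The observed statistic is the mean-score
difference in percentage points,

$$D = 100\,(\bar b - \bar a).$$

Each of $R$ resampling iterations (study value $R = 100{,}000$) draws,
without replacement, a pseudo-*b* of size $|b|$ from the pooled items;
the leftover forms the pseudo-*a*; the permuted difference $D^*$ is
recomputed. The p-value is the fraction of iterations with $D^* \ge D$
(one-sided) or $|D^*| \ge |D|$ (two-sided) — the "extreme count"
divided by $R$, with no continuity correction, so $p = 0$ is possible
and is printed as $< 1/R$.

Numerical choices: because the data are binary, $D^*$ is a strictly
increasing function of the success count $k$ landing in pseudo-*b*, so
extremity is decided in exact integer arithmetic ($k \ge k_b$
one-sided; $|kn - Kn_b| \ge |k_b n - K n_b|$ two-sided, with $K$ the
pooled success count and $n$ the pooled size). No floating-point
comparison ever decides a tie. The resampling loop is compiled (a
partial Fisher–Yates shuffle driven by R's RNG), so a 100,000-resample
test on 275 + 275 items runs in about a second and is bitwise
reproducible from its seed. If the pooled values are constant the
observed difference is 0 and the inclusive rule returns $p = 1$.

`exact_permutation_test()` is the correctness oracle: it enumerates the
distribution of $k$ with hypergeometric multiplicities
$\binom{K}{k}\binom{n-K}{n_b-k}$ via `lchoose`, i.e. the exact
permutation null. By default it refuses inputs with more than $10^7$
distinct assignments and points to the Monte Carlo mode; `max_enum`
lifts the cap, since for binary data the collapsed enumeration over $k$
is cheap at any size. The test suite checks it against brute-force
subset enumeration (`utils::combn`) and against `stats::phyper`, and
checks the Monte Carlo engine against it at 4 binomial standard errors.

### Sidedness

Within-IIDR comparisons default to the one-sided alternative in the
wide − default direction: the study reports improvements, and its
extremity rule counts permuted differences *equal to or greater than*
the observed one. Between-group comparisons fix the sides as
(preCSPL65, preCSPL80); the observed differences run negative (the
preCSPL65 group scores higher), and no direction is privileged a
priori, so `run_study()` uses the two-sided rule on that axis. Both
choices are arguments, not constants. No multiplicity adjustment is
applied anywhere, matching the reporting conventions the pipeline
mirrors (significance stated at p < 0.05 and p < 0.01, strict
inequality).

### Pooling

Group-level comparisons concatenate item outcomes across the selected
subjects (e.g. 11 × 25 = 275 word items per side for the all-subjects
tests; 125 vs 150 items for a between-group word comparison with 5 vs 6
subjects). This is the only reading under which the stated resample
units — 25 words, 60 morphemes per subject — aggregate meaningfully at
group level. A within-subject (paired) permutation variant would be a
different test; it is deliberately not implemented rather than guessed.
Pooling treats items as exchangeable across subjects under the null,
which ignores subject-level clustering; the type-I calibration reported
by the acceptance suite shows the test is, if anything, slightly
conservative at these sizes (rejection rate ≈ 0.045 at α = 0.05).

## The synthetic cohort generator

The original item data were not deposited, so the pipeline runs on
synthetic cohorts. The generator emulates the design exactly: 5 + 6
subjects, 16 cells per subject (8 conditions × 2 IIDRs), 25 or 60
binary items per cell. Items are independent Bernoulli draws whose cell
probabilities are the published group-level mean scores divided by 100
(the bundled `study_preset()`); e.g. preCSPL65 words-in-noise at 65 dB
is 0.704 under the default IIDR and 0.776 under the wide one, and the
near-floor preCSPL80 cells at 80 dB in noise are 0.007 and 0.032.

Between-subject heterogeneity is a logit-normal subject effect: each
subject draws $u_s \sim N(0, \sigma)$ once, and every cell's effective
probability is $\mathrm{logit}^{-1}(\mathrm{logit}(p) + u_s)$; base
probabilities of exactly 0 or 1 bypass the transform so floor and
ceiling cells stay degenerate. The study gives no subject-level
dispersion, so σ defaults to 0.2 on the logit scale — large enough that
subjects are visibly heterogeneous (roughly ±10 percentage points
around mid-scale cells across a group), small enough to preserve the
published complete separation of the two groups' noise scores at 65 dB
under the default setting, which the suite verifies in ≥ 95% of
generated cohorts. Because the same $u_s$ shifts both IIDR cells of a
subject, within-subject contrasts are only weakly affected by σ.

Randomness is hierarchical: every subject effect and every
subject-by-cell list draws from a private stream whose seed is derived
from the config seed and the cell's label, so cohorts are bitwise
reproducible and adding a condition or subject never perturbs the other
cells' draws.

What the generator does **not** model: item difficulty. The test
batteries' lists are known not to be identically distributed — item
difficulty varies across lists and subjects — but no distribution for
it is available, so items within a cell are exchangeable by
construction. Passing tests therefore validate the statistical engine
and pipeline on data satisfying the permutation null's exchangeability
assumption; they cannot certify behaviour under real item-difficulty
structure. Learning/order effects and any psychometric link between
accuracy and presentation level, SNR or C-SPL are likewise out of
scope: probabilities are configured per cell, not derived.

## The study pipeline

`run_study()` executes the full matrix: 24 within-IIDR tests (8
conditions × groupings all/preCSPL65/preCSPL80) and 16 between-group
tests (8 conditions × 2 fixed IIDRs). Each comparison runs on its own
RNG stream derived from the base seed and the comparison label, so
reports are reproducible and row-order-insensitive. Reported means are
unweighted means over subjects of per-subject percent scores, which at
equal items per subject coincide with the pooled item means the test
uses; the suite asserts that equality. `significance_pattern()`
collapses a report to p < α flags and can diff them against an expected
pattern such as `expected_pattern_all_subjects()` (wide IIDR improves
everything except sentences in quiet at 65 dB).

## Problem sizes and stochastic checks

The suite generates cohorts at the full study size (7,480 item rows;
generation is milliseconds). Calibration checks average 60–200 cohorts;
oracle-agreement checks use 100,000 resamples at pooled sizes ≤ 16;
type-I calibration simulates 2,000 null datasets at the study's pooled
sizes (275 and 660 per side) through the exact tail. The headline
stochastic check — the all-subjects words-in-noise improvement at 65 dB
detected at p < 0.01 — uses 50 independent cohorts at 100,000 resamples
each. At these calibrated effect sizes its per-run success probability
is about 0.94: the realized mean difference across cohorts is roughly
normal with mean ≈ 16 and SD ≈ 4.2 percentage points (irreducible
item-level binomial noise at 275 items/side), while p < 0.01 needs
≈ 10 points. A ≥ 95%-of-runs requirement therefore sits on the wrong
side of that rate and fails for about half of seed choices; this is a
property of the published effect size at the published sample size, not
of any tunable parameter (σ does not move it), and the package reports
the rate rather than adjusting the conditions.

## Known limitations

* Items are exchangeable within cells; real lists have difficulty
  structure the permutation null would partially absorb but the
  generator cannot create.
* The pooled test ignores subject clustering (see above); a paired
  variant is future work.
* Probabilities near the floor (0.007) make some between-group cells
  effectively deterministic; the inclusive extremity rule handles the
  resulting ties exactly, but Monte Carlo p-values of 0 should be read
  as < 1/R, not as exact zeros.
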