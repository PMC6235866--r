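---
title: "Decoding vowel identity during perceptual constancy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding vowel identity during perceptual constancy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vowelconstancy)
```

## The problem

Perceptual constancy is the ability to recognize an object across
identity-preserving transformations of the sensory input — here, a vowel's
identity across changes in fundamental frequency (F0), sound level, location
and voicing. In the underlying behavioral paradigm, ferrets discriminate two
synthesized vowels in a two-choice task while one orthogonal acoustic
dimension is roved per session; auditory-cortical units are recorded during
behavior and passive listening. This package re-implements the analysis
chain for that paradigm — stimulus synthesis, a single-unit spike-distance
decoder with response-window optimization, permutation significance,
temporal-multiplexing and engagement contrasts, matched sound/choice/accuracy
decoding, and a confidence-weighted population decoder — together with a
synthetic-data generator so that every stage is testable against known ground
truth without access to the original recordings.

## Stimulus synthesis

Vowels are generated source–filter style: a glottal click train (voiced) or
white noise (whispered) excites four two-pole resonators in parallel, one per
formant. Each resonator has poles at radius `exp(-pi * BW / fs)` and angle
`2 * pi * F / fs`, with its numerator scaled for unity gain at the formant
center; the four outputs are summed with equal weights. This is the simplest
filter realization that reproduces the specified formant peaks without
imposing an arbitrary spectral tilt; no source-spectrum compensation (e.g.
for glottal roll-off) is applied, since no normalization convention is part
of the paradigm. Parallel summation lets neighboring resonator skirts
interfere, which can shift a measured peak by a few hertz relative to the
nominal formant — the tests bound this shift at 25 Hz on a 2 Hz analysis
grid.

Tokens are 250 ms, ramped with 5 ms raised-cosine ramps, and presented twice
with a 250 ms silent interval (`two_token_stimulus`). The four task vowels
(`vowel_table()`) use the paradigm's formant frequencies with shared
bandwidths of 80, 70, 160 and 300 Hz, F0 in {149, 200, 263, 330, 459} Hz,
and levels from 45 to 82.5 dB.

Two conventions are package choices rather than physical facts:

* **Digital level.** Absolute dB SPL is not calibratable in software, so
  `set_level()` anchors 70 dB at an RMS of 0.05 full scale; every other
  level is the exact relative gain, preserving printed level differences.
* **Sample rate.** 48 kHz by default (any rate at least twice F4 is
  accepted); click-train phase starts at sample zero and the period is
  rounded to the nearest sample, making voiced synthesis deterministic.

## The synthetic-data generator

`generate_trial_table()` emulates the behavioral session: a balanced vowel x
orthogonal-feature grid, Bernoulli outcomes under a configurable
per-condition probability of correct response, whispered probe trials on
10–20% of trials (any response rewarded, no correction follows), and a
correction trial inserted after every test-trial error. Choice follows from
vowel, outcome and the stimulus–response contingency, exactly as in the
task.

`unit_tuning()` parameterizes a unit as a baseline rate plus feature-specific
temporal kernels. Each kernel is a half-cosine bump over
`[latency, latency + duration]` with a per-feature-value gain in Hz — smooth,
compactly supported, and controlled by two interpretable parameters. Because
each feature can have its own latency, a single unit can carry vowel
information early and F0 information late: the temporal-multiplexing
structure the decoder is meant to recover. Behavioral signals are expressed
as kernels on the choice and accuracy columns, and task engagement scales
the evoked (not baseline) rate during stimulus presentation, matching
suppression observed during, but not before, sounds.

Spikes are drawn by inhomogeneous-Poisson thinning over the covered epoch
[-0.5, 1.5] s (`sample_spikes`), so counts in any interval are Poisson with
the integrated-rate mean, and the full decoding grid plus the 450 ms and
300 ms baselines are populated. What the generator deliberately omits:
correlated variability across units, non-Poisson spiking statistics
(bursting, refractoriness), adaptation across trials, and receptive-field
structure beyond the injected kernels. Tests passing on this generator
therefore establish that the analysis recovers the structure it assumes —
chance calibration, type-I control, latency-order recovery, weight bounds,
population saturation — not that real cortical data satisfy those
assumptions.

## The single-unit decoder

`locv_decode()` is a template decoder with leave-one-out cross-validation:
for each trial, the template for every stimulus class is the mean
peri-stimulus time histogram of all *other* trials, binned within the
decoding window; the trial is assigned to the nearest template in Euclidean
distance, with ties resolved by a seeded uniform guess. Performance is the
percentage of trials whose label is recovered. The leave-one-out templates
are computed by a closed-form adjustment — the distance to a unit's own
hold-out template equals `nc/(nc-1)` times its distance to the full class
mean — so optimizing over 1550 windows and 100 label shuffles stays cheap.

Numerical choices:

* **Bin width** inside the window is 10 ms by default, matching the grid's
  duration quantum; a single-bin count mode (`bin_width = duration`) is
  available and is the population-decoder default.
* **Distances** are computed on counts/bin; Euclidean distance on rates
  differs only by a constant factor and cannot change the argmin.
* **Tie detection** uses a 1e-9 relative tolerance, since template means are
  small rationals computed in floating point.
* **Class floor**: five trials per class, the study's minimum, relaxable for
  worked examples via `min_trials`.

`decode_surface()` evaluates the full window grid — start times from -0.5 to
1 s and durations from 10 to 500 ms — and reports the best cell, breaking
ties toward the earliest start and then the shortest duration. The paradigm
is usually described with a 0.1 s start step alongside a 1550-window total,
which are inconsistent (a 0.1 s step gives 800 windows); the default grid
uses the 0.05 s step that yields 1550, with the 0.1 s variant one argument
away.
Windows apply to continuous trial time, so spikes in the inter-token gap are
included when a window spans it.

## Significance: a Gaussian-parameterized permutation test

Because the best window is *selected* per unit, the relevant null
distribution is the best performance over the same grid after shuffling the
decoded labels — each shuffle repeats the full optimization, which pushes
null performance well above nominal chance. `shuffle_null()` runs 100 such
shuffles; `gaussian_tail_p()` fits a normal to them and reports the
upper-tail probability of the observed performance, clamped to (1e-10, 1].
The parametric fit trades the empirical null's granularity for two orders of
magnitude fewer shuffles. A unit is *informative* when p < 0.05 (strict).
No family-wise correction is applied across units, matching the paradigm's
convention; the reported informative fractions should be read accordingly.
The acceptance suite measures the resulting empirical type-I rate on
stimulus-independent units; the Gaussian approximation to the
max-over-windows statistic (which is mildly right-skewed) makes the test
approximately, not exactly, nominal.

`dual_feature_permutation()` shuffles unit identity of one informative-flag
set to ask whether jointly informative ("dual-feature") units exceed chance;
under the null the joint count is hypergeometric, which the tests verify.
The p-value is the fraction of permuted counts strictly above the observed
count; when the permutation distribution is degenerate at the observed value
(e.g. one flag set all TRUE) the strictly-above rule would report 0 from
zero evidence, so the function returns 1 in that case, and a ties-inclusive
variant sits behind `include_ties`.

## Timing, engagement, matched decoding, population decoding

**Center times.** The timing statistic is the best window's center
(start + duration/2), invariant to bin width. Paired two-group comparisons
(dual-feature units, engaged-vs-passive) use the Wilcoxon sign-rank test
with the median paired difference; unpaired ones use the rank-sum test with
the difference of medians; multi-group comparisons use Kruskal–Wallis. For
post-hoc pairwise contrasts the package uses pairwise rank-sum tests with
Holm correction — the standard R idiom — in place of the Tukey–Kramer
adjustment common in MATLAB toolchains.

**Engagement.** `engaged_passive_contrast()` compares onset firing rate and
decoding per state, either in a fixed 100 ms onset window or with each
state's own window optimization. Baseline normalization
(`normalize_to_baseline`) is a ratio by default — the common reading of
"relative to baseline" — with a difference mode behind a flag; zero-baseline
units are flagged undefined and excluded from ratio analyses.

**Matched datasets.** `build_matched_dataset()` removes correction,
whispered, sub-level-floor and fast-response trials, then balances the
vowel x choice x outcome cells at the minimum occupied-cell count N (error
if N < 5). Under a fixed contingency only four of the eight cells can occur,
and balancing those makes the priors of all three decoded variables uniform
and behavioral percent correct exactly 50. The response-time exclusion is
anchored to first-token onset by default; anchoring to second-token onset
(0.5 s later) is an equally defensible convention and is available via
`rt_anchor`.

**Population decoding.** Each member unit contributes its leave-one-out
estimate weighted by the confidence score

$$w = 1 - \frac{d_{\min}}{\sum_{j=1}^{n} d_j},$$

where the d_j are its spike distances to the n class templates; w is bounded
in [1 - 1/n, 1], reaching the floor exactly when all distances are equal.
Summed weights per class decide the trial (argmax, seeded ties). Within the
100 ms population window the response is a single spike count — the
shortest-duration convention consistent with the unit decoder — and
populations are drawn from the pool of units ranked by correct-trial vowel
decoding, up to 74 units with 100 sampled combinations. The exact
subpopulation from which combinations should be drawn is a free choice;
this package uses the ranked pool itself and records that choice here. At the
maximum size equal to the pool size only one combination exists, and the
sampler returns unique combinations where the pool permits fewer than
requested.

**Behavior.** `constancy_summary()` reports per-value percent correct with
binomial tests against 50% and a logistic regression of accuracy on the
orthogonal feature (constancy = non-significant feature effect at 0.05).
`generalization_test()` grows windows from the first exposure to a novel
feature value and reports the smallest window significant against a
randomized-response null at alpha 0.001; the exact binomial tail (an
error-free record reaches criterion at exactly ten trials, since
0.5^10 < 0.001) backs the Monte-Carlo mode. Nested-from-first windows follow
the stated procedure; a sliding variant exists behind a flag.

## Problem sizes and determinism

The test suite and the acceptance script run on desk-scale simulations
chosen to finish in minutes while leaving the statistical checks
well-powered: chance calibration uses 100-trial units with 200 label
shuffles; type-I calibration uses 100–200 stimulus-independent units over a
reduced 30-window grid with 100 shuffles each; latency-recovery uses 10–14
units; population saturation uses cohorts of 40–74 units with 20 trials per
vowel. The `analysis/` drivers use a 28-unit, ~270-trial session and a
coarsened 70-window grid for the same reason; the full 1550-window grid is
the package default. Every stochastic step takes an explicit seed, and all
randomness flows through R's generator, so identical seeds reproduce results
bit-for-bit.

## Known limitations

* The decoder models no response variance (by design — it must work down to
  five trials per class); a likelihood-based classifier would be more
  efficient on large datasets.
* The Gaussian null is an approximation to a max statistic; its type-I rate
  is near, not exactly at, the nominal level.
* The generator's independence across units means population-decoding
  results here say nothing about noise correlations, which can matter in
  real populations.
* Headline quantities from the original recordings (informative-unit
  percentages, mean decoding levels, specific timing differences in ms)
  depend on the ferret data and are not reproduced; the package's claims are
  calibration and recovery properties on synthetic ground truth.
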