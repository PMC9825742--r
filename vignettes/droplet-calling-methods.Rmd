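---
title: "Model-based droplet calling and methylation normalization: methods"
author: "dropcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based droplet calling and methylation normalization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Droplet digital PCR partitions a sample into thousands of droplets, each
hosting an independent PCR reaction. After amplification, droplets that
contained the target fluoresce brightly (the *positive* cloud) while empty
droplets form a dimmer *negative* cloud, and the target's absolute
concentration follows from the fraction of positive droplets. Everything
therefore hinges on placing one threshold per well and channel on the
amplitude axis. Methylation assays make this harder than usual: probe and
primer design is constrained by the bisulfite-converted sequence, so
*rain* — droplets strewn between the clouds — is common and often cannot be
optimized away. On top of that, wells can contain *destroyed* droplets with
amplitudes near zero, and the negative baseline can shift from well to
well. Vendor software with fixed or manually placed thresholds handles
these failure modes poorly, and manual thresholding is not reproducible.

`dropcall` automates the whole path from per-well amplitude CSV files to a
normalized methylation level: robust outlier removal, a model-based
threshold, Poisson quantification, and normalization against an internal
control, with every free parameter exposed in a config object and recorded
in the run manifest.

## The calling procedure

Per well and per channel, `call_well()` composes four steps.

**1. Destroyed-droplet removal.** Destroyed droplets present as a sparse
tail far below the negative cloud. We compute the median and MAD of the
lower half of the amplitude distribution (values at or below the overall
median — a statistic the positive cloud cannot influence) and remove
droplets below `median − k·MAD` with `k = 5` by default. A MAD of zero
(degenerate, constant amplitudes) removes nothing and flags `zero_spread`;
removing *every* droplet flags the well as unusable. Removed droplets are
excluded from both the positive and the total count: a ruptured droplet is
not a valid partition, so it carries no Poisson information.

**2. Mixture fit.** Amplitudes are modeled as a univariate Gaussian
mixture. Gaussian clouds are the standard approximation for ddPCR
amplitude clusters, and one negative plus one positive component is the
expected geometry, so we fit 1 to `max_components` (default 2) components
(equal- and unequal-variance parameterizations) by EM via `mclust` and
select the component count by BIC. Components are reported in
ascending-mean order; the lowest-mean component is read as the negative
cloud. The RNG seed is fixed (`rng_seed`, default 1) immediately before
the fit, so that the subsampled initialization used on large wells is
reproducible and identical inputs give bit-identical calls.

**3. Threshold selection.** Three rules are available:

* `mean_plus_k_sd` (default): negative-component mean plus `k_sd` standard
  deviations, `k_sd = 5`. This rule is exactly shift-equivariant — adding a
  constant to all amplitudes moves the threshold by that constant — which
  is what makes the caller indifferent to baseline shifts.
* `quantile_of_negative`: the `negative_quantile` (default 0.995) Gaussian
  quantile of the negative component.
* `component_intersection`: the equal-density point between the extreme
  components.

When two components are present the threshold is guaranteed to lie
strictly between the two component means; if the configured rule lands
outside that interval we fall back to the equal-density intersection, then
to the midpoint between the means. When only one component is selected the
well is treated as target-free and the threshold is placed at
`mean + k_sd·sd` of that single (negative) component — deliberately far in
its upper tail, and deliberately *not* range-checked against the observed
maximum: an empty well should yield approximately zero positives, and with
`k_sd = 5` the expected number of Gaussian negatives above the threshold
is about `n · 2.9e-7`, i.e. essentially none at typical droplet counts.

**4. Labeling.** Strictly greater than the threshold is `positive`;
everything else retained is `negative`, including exact ties. Rain is
intentionally not modeled as a third component: between-cloud droplets are
simply split by the threshold. An explicit rain component would trade a
well-understood, monotone rule for a fragile fit on a population with no
stable distributional shape.

A well whose retained droplet count falls below `min_droplets` (default
8000, ordinary QX-plate practice) is flagged `low_droplet_count` and gets
no threshold, but it is never silently dropped: it appears in the results
table and manifest with its flags. Stage failures likewise degrade to
flags rather than aborting the plate.

Manual correction is first-class: `override_threshold()` (in memory) and
`apply_override_file()` (against a finished run directory) relabel the
retained droplets of one channel at a user-chosen threshold, re-quantify
and re-normalize only the affected wells, preserve the removal labels from
filtering, and record the override in the manifest with
`threshold_source = "manual"`.

## Quantification

With `k` positives among `n` retained droplets, random partitioning gives
the Poisson occupancy estimate

&lambda; = −ln(1 − k/n)  copies per droplet,

and the concentration is &lambda; / v with v the droplet volume
(default 0.85 nL, the Bio-Rad QX200 partition volume, config-exposed), in
copies/µL. `k = n` is reported as a flagged saturation, not a number.
Confidence intervals are Wilson score bounds on the positive fraction
(no continuity correction) pushed through the monotone map
−ln(1−p)/v; Wilson was chosen because it behaves well at `k` near 0, the
regime low-concentration methylation targets (liquid biopsies especially)
actually occupy, where Wald intervals collapse.

## Normalization

Methylation levels are reported relative to a channel-2 internal control:

value = (channel-1 concentration / channel-2 concentration) × c,

with `c = 100` for a single-gene control and `c = 400` for the 4Plex
panel. The 4Plex amplifies four single-copy genes on different
chromosomes, so its concentration counts four control copies per genome
equivalent; scaling by 400 puts its values on the same percent-like scale
as single-gene normalization. Values above 100 are reported as computed
(chromosomal aberrations can genuinely push target above control) with a
QC note, never clipped. A zero, missing or saturated control yields a
flagged undefined value instead of an infinity, so one failed control well
cannot poison a plate CSV. Without an internal control (`ch2 = FALSE` in
the pipeline) the raw channel-1 concentration stands alone and the
normalized column stays empty.

## The simulator, and what passing tests do not show

`simulate_well()` / `simulate_plate()` generate wells in the exact CSV
dialect the readers consume, with ground truth. Occupancy is Bernoulli
per droplet with probability 1 − e^(−&lambda;); empty droplets draw from
the negative cloud, occupied from the positive cloud. Defaults describe
the study conditions used throughout the tests: 20,000 droplets per well,
negative cloud 2000 ± 120 and positive cloud 8000 ± 180 arbitrary
fluorescence units on both channels, target &lambda; = 0.1 against a
control at 0.2. No instrument amplitudes are published for this geometry;
these values were chosen once to resemble a routine two-cloud QX well
(separation ≈ 33 negative-cloud SDs) and are documented as synthetic.
Failure modes are opt-in: a `rain_fraction` of occupied droplets drawn
uniformly between the cloud means (uniform rain is the hardest case for a
fixed threshold — any unimodal rain concentrated near a cloud is easier),
a `destroyed_fraction` of droplets forced to amplitudes in [0, 100] in
*every* channel (a ruptured droplet is ruined physically, not per
channel), and a constant `baseline_shift`.

The simulator does not emulate channel crosstalk, droplet-volume
variability, amplitude drift within a run, or heavy-tailed/skewed clouds.
Tests passing on simulated plates therefore demonstrate the procedure's
correctness under the stated model — exact truth recovery at ≥ 10 SD cloud
separation, robustness to destroyed droplets and baseline shifts, ratio
recovery under 5% uniform rain — not calling accuracy on every real
instrument artifact.

## Numerical choices and problem sizes

* `−log1p(−k/n)` rather than `−log(1 − k/n)` for small-`k` accuracy;
  `k = 0` returns exactly 0.
* Ties at the threshold are negative, matching the strict "greater than"
  definition of a positive droplet.
* Results CSVs print floats with 4 decimal places and counts as integers,
  which makes write → read → write a byte-exact fixed point and lets
  override-then-revert reproduce a results file bit-for-bit.
* Mixture fits refuse to run below `min_droplets`; property tests that
  need many fits use wells of 2,000–15,000 droplets with a lowered floor,
  while end-to-end checks use full-size 10,000–20,000-droplet wells — the
  sizes at which binomial standard errors make the stated tolerances
  meaningful.
* Per-well thresholds are the default and the only mode: pooling wells of
  a shared target would couple wells across the plate and defeat the
  per-well robustness this package exists for; the label exports contain
  everything needed to impose a shared threshold via the override path.

## Known limitations

Two-channel wells are analyzed per channel; there is no 2-D joint-channel
clustering, no explicit rain component, no cross-plate threshold
transfer, and no merged-well quantification. The 4Plex control is treated
as a single channel-2 signal (no per-assay decomposition). Sample-sheet
`TargetType` values are carried as free text and not interpreted.
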