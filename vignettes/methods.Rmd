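---
title: "Methods: social attention versus physical saliency in scene viewing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social attention versus physical saliency in scene viewing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenegaze)
```

## The scientific question

When people look at a natural scene, their earliest eye movements are pulled
both by low-level physical conspicuity (colour, intensity and orientation
contrast) and by semantic content — most strikingly by other people, and by
heads in particular. Disentangling the two requires stimuli in which the
social regions are *not* the most physically salient parts of the image, an
exhaustive region-of-interest (ROI) labelling of every pixel, and statistics
that correct for the very different sizes of the regions being compared.

`scenegaze` implements that analysis end to end for a two-task design
(free viewing versus detecting people as fast as possible), together with a
synthetic-data generator that produces scenes, social masks and 1000 Hz gaze
recordings with known ground truth, so that every stage of the pipeline can
be validated without access to any proprietary recordings or copyrighted
photographs.

## Saliency model

`compute_saliency_map()` scores each pixel by how strongly it differs from
its surround in three feature families: intensity, colour opponency
(red–green and blue–yellow, with yellow as the mean of red and green) and
orientation energy (quadrature Gabor pairs at 0°, 45°, 90° and 135°; four
orientations match the model family this analysis descends from, which does
not fix the count). Feature maps are computed at analysis scales 0.5, 0.25
and 0.125 of the input resolution, combined on a common reference lattice at
0.027 of the input resolution (all defaults of `saliency_params()`),
averaged within and then across features, resized back to the input
resolution by bilinear interpolation and rescaled to a maximum of 1.

Two backends are provided:

* `centre_surround` (default): per scale, the absolute difference between a
  feature map and its Gaussian-blurred surround (sigma =
  `surround_sigma_frac` of the smaller image dimension), followed by a
  global-uniqueness weighting `(1 - mean)^2` that suppresses near-uniform
  maps — a cheap stand-in for iterative within-map normalization.
* `graph_activation`: the reference lattice is treated as a fully connected
  graph with transition mass `|v_i − v_j| · exp(−d²/2σ²)` (σ =
  `graph_sigma_frac` × the larger lattice dimension, default 0.15); the
  activation map is the equilibrium distribution of the induced Markov
  chain, found by power iteration (tolerance 1e-9, cap 10,000 iterations).
  The edge-weight bandwidth and channel weighting of published graph-based
  models are not printed anywhere we could verify against, so these are
  exposed as configuration with documented defaults and no claim of
  numerical fidelity to any specific binary.

A zero-variance image yields the all-zero map: "different from the surround"
is vacuous there, and zero is the canonical constant. Both backends agree on
the argmax region for single-blob toy images (tested against a brute-force
block-average centre–surround oracle).

## ROI partition

`build_roi_partition()` labels every pixel exactly once: hand-drawn (here:
generated) head masks first, body masks next, and the remaining non-social
pixels are split at the 8th decile of their saliency values — values
*smaller or equal to* the decile go to the `lower` region, the rest to
`higher`. Deciles are computed over the **non-social pixels only**: with
2.1% head and 8.9% body coverage this yields a lower-saliency area of
0.8 × 89% ≈ 71.2% of the image, which is the only reading consistent with
typical coverage statistics of such stimulus sets; a `deciles_over = "all"`
switch provides the alternative reading. The decile uses the inverse-ECDF
(type 1) quantile, so with distinct values and no social pixels `lower`
covers exactly 80%. The partition depends only on the rank order of
saliency values, and `relative_roi_saliency()` (mean saliency in the region
over mean scene saliency) conserves exactly: the area-weighted mean over any
exhaustive partition is 1.

## Event parsing

`detect_events()` classifies saccades by a velocity threshold of 30 deg/s
*or* an acceleration threshold of 8000 deg/s², sustained for at least 4 ms.
Velocity is a five-sample central difference of position converted with the
small-angle deg-per-pixel factor at screen centre; acceleration applies the
same five-sample operator to the speed. The five-sample smoothing matters:
with a plain two-point difference, ordinary tracker noise (0.2 px RMS at
1000 Hz) alone would cross both thresholds. Commercial parsers are
proprietary, so this parser is validated against the synthetic generator's
truth log instead: on noiseless traces the detected saccade count equals the
generated count exactly, and fixation boundaries agree within a few
milliseconds.

Blinks are runs of missing pupil data; for classification they are padded by
25 ms on each side to absorb pupil-edge position artefacts (standard
practice, configurable), while `blink_fraction()` uses the raw missing-pupil
time, which is what the 20% exclusion rule is defined on. Time not inside a
saccade or padded blink is fixation; no minimum fixation duration is
imposed. Off-screen fixation centroids are kept but flagged; ROI assignment
downstream maps them to `NA`.

## Preprocessing

`compute_baseline()` averages the valid samples in the 300 ms window
directly before scene onset, when the participant fixates the central cross.
`recursive_outlier_removal()` is applied to each participant's baseline x
and y distributions across trials: the current minimum and maximum are
temporarily removed; either is discarded permanently if it lies more than
3 sample standard deviations from the mean of the rest, iterated until
neither is. Both extremes may fall in one iteration; recursion stops when
fewer than three values would remain after the temporary removal (the
remainder's s.d. becomes degenerate), and a zero-spread remainder only
expels extremes that actually differ from it. The retained set is
permutation-invariant. Trials with missing or discarded baselines, and
trials with ≥ 20% of the scene presentation contaminated by blinks, are
excluded (`exclude_trials()`, with an audit of one reason per dropped
trial); surviving fixations are shifted so the baseline maps onto screen
centre (`drift_correct()`).

## Fixation statistics

`area_normalized_frequency()` computes, per participant, task, ROI and
fixation index (1–5, plus a pooled "6+" bin), the relative frequency that
the ROI received the index-th fixation — numerator and denominator both
restricted to on-screen fixations, the denominator being the number of
trials with a valid index-th fixation since the partition is exhaustive —
divided by the mean pixel area of the ROI across the denominator trials.
"First five fixations" means the first five fixation events *starting* at or
after scene onset; the fixation already in progress at onset is index 0 and
skipped. Scores therefore have units 1/px and larger regions are not
mechanically favoured.

`first_entry_latency()` records, per trial and ROI, the onset latency of the
first fixation landing in the ROI, and takes the median per participant,
task and ROI over trials with at least one valid fixation on that ROI. The
`conditional_on_first` variant keeps only trials whose very first scene
fixation landed in the ROI — the purest measure of first-glance capture.

## Inference

* `rm_anova()`: fully within-subject ANOVA via orthonormalized contrast
  projections. For effects with more than one numerator df the
  Huynh–Feldt epsilon is computed from the contrast covariance
  (`(n·d·ε_GG − 2)/(d·(n − 1 − d·ε_GG))`, clamped to 1 — the form used by
  the `car` package, against which the implementation is tested on 1-, 2-
  and 3-factor designs) and applied to the degrees of freedom of every
  multi-df effect regardless of a sphericity pretest. Partial eta squared is
  `SS_effect/(SS_effect + SS_error)`.
* `paired_t()` reports the effect size `d_z`; `bonferroni_alpha()` divides
  the alpha level (this analysis corrects alpha levels, not p-values).
* `harrell_davis_quantile()` is the Beta-weighted sum of order statistics;
  `shift_function_dependent()` compares paired conditions at the quartiles,
  resampling *pairs* with replacement (1000 bootstrap samples by default) —
  resampling participants preserves the dependence that the paired design
  creates. The bootstrap p-value is `2·min(P(diff* > 0), P(diff* < 0))`
  with ties split half into each tail; the originating package's exact
  small-sample adjustment is unpublished, so ours is documented here and is
  seed-stable.
* `required_n_paired_t()` walks the noncentral-t power curve
  (ncp = `d_z·√n`, df = `n − 1`) upward and returns the smallest n meeting
  the target power; at `d_z = 0.50`, power 0.85, one-tailed α = 0.05 it
  returns 31.

One-tailed power planning and two-tailed testing coexist in this literature;
both alternatives are supported everywhere and never guessed.

## The synthetic generator

`random_scene_spec()`/`generate_scene()` draw scenes with one or two person
figures (muted body ellipse, skin-toned head ellipse) and two to four
high-contrast ring distractors over a lightly textured grey background. The
distractors are deliberately more conspicuous to the saliency model than the
social regions — the property that makes the social-versus-salient contrast
meaningful — and head/body coverages land in the low-percent range typical
of social-scene photograph sets.

`generate_gaze_trial()` emulates the trial structure: 1 s central fixation,
10 s scene, 1000 Hz sampling, with 200 ms of post-offset recording so
movements in flight at offset complete inside the stream. The first saccade
launches at a truncated-normal latency (means 280 ms free viewing / 260 ms
social detection by default — a −20 ms task effect) towards a point drawn
uniformly from a ROI selected by the task's first-target probabilities
(defaults: head .35/.50, body .16/.22, lower .23/.11, higher .26/.17 for
free viewing / detection). Subsequent targets come from a task-independent
map (head .30, body .25, lower .25, higher .20): the design constrains only
early fixations, so later ones carry no task signal. Saccades follow a
symmetric raised-cosine velocity profile with a main-sequence-like duration
(21 ms + 2.2 ms/deg), giving amplitude-scaled peak velocities; landing
points closer than 15 px (~0.75°) are redrawn, since sub-degree saccades
would fall below the detection threshold by construction and essentially do
not occur in scene viewing. Blinks arrive as a Poisson process (0.02 Hz,
~150 ms) with missing pupil and frozen position; a constant per-trial
calibration drift (s.d. 5 px) shifts everything, and with probability 0.02
the participant mis-fixates the cross, displacing only the pre-onset
samples — the fault the baseline outlier removal exists to catch.
Between-participant jitter (latency mean s.d. 8 ms; head-probability logit
s.d. 0.3) creates realistic individual differences. Position noise defaults
to 0.2 px RMS (~0.01°, the precision class of a good 1000 Hz video
tracker).

The default scene resolution is 640 × 480 px mapped onto a
30.6 × 23.0 cm stimulus area viewed from 52.5 cm (32.5° × 24.7°). With
~3 × 10⁵-px images the area-normalized scores come out around 10⁻⁴–10⁻⁶
per px; published values from ~10⁶-px stimuli are proportionally smaller,
which is why the package's tests assert relative patterns, never absolute
score magnitudes.

What the generator does **not** emulate: photorealistic image statistics,
smooth pursuit, microsaccades, main-sequence curvature or velocity-profile
asymmetries, tracker-specific noise spectra, or emotional-valence
manipulations of scenes. Passing tests therefore demonstrate that the
pipeline measures what it claims on data satisfying its assumptions, not
that any particular empirical effect exists in real recordings.

## Numerical choices and degenerate inputs

* Decile threshold: type-1 (inverse ECDF) quantile with the ≤ tie rule;
  cutoff 0 empties `lower`, cutoff 10 empties `higher`.
* Constant images produce all-zero saliency maps; near-constant channels on
  the graph backend are snapped to zero to keep resampling ripple
  (~1e-16) from being amplified into a spurious equilibrium.
* `paired_t()` on identical inputs returns t = 0, p = 1; a constant nonzero
  difference is an error, not an infinite statistic.
* `rm_anova()` refuses incomplete subject × cell grids and warns on zero
  error sums of squares; sample s.d. uses the n − 1 denominator throughout.
* All stochastic routines take explicit seeds; `run_study()` derives every
  stage seed from the single master seed, and re-running with the same
  configuration is bit-identical.

## Problem sizes used by the test suite

The routine suite exercises the generator-versus-parser agreement on 150
noiseless trials with 3 s scenes, distribution recovery on 2,000
short-scene trials, and the full pipeline on an 8-participant,
8-trials-per-task, 18-scene study. The acceptance suite runs the complete
33-participant × 40-trials-per-task × 80-scene simulation once (a few
minutes on one core), checks type-I calibration on 10,000 null replicates
and shift-function coverage on 200 replicates at n = 33. These sizes were
chosen so the full suite completes comfortably on a laptop core while
keeping every Monte-Carlo margin far from its decision boundary.

## Known limitations

* The event parser approximates a proprietary one; agreement is established
  against synthetic ground truth only.
* The graph-activation backend omits the second ("concentration")
  normalization pass some graph-based models apply; the ROI partition
  consumes only rank information, which both backends agree on for the
  blob-like structure the generator produces.
* The `"6+"` fixation bin pools events rather than averaging per-index
  scores; with the long scenes used here the two differ negligibly.
* Latency medians on few contributing trials are noisy; the package reports
  the contributing trial count alongside every median so users can filter.
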