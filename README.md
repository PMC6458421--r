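# scenegaze

Quantifying how early gaze prioritizes **social scene regions** (heads,
bodies) over **physically salient regions** during free viewing versus an
explicit social-detection task.

When observers inspect natural scenes, the first few fixations are contested
between bottom-up conspicuity — locations that differ from their surround in
colour, intensity or orientation — and social meaning. Separating the two
requires stimuli whose most physically salient parts are *not* the people,
an exhaustive labelling of every pixel, and statistics that correct for
region size. `scenegaze` implements that full analysis pipeline for
1000 Hz eye-tracking data, plus a synthetic-data module that generates
scenes, social masks and gaze recordings with ground truth, so every stage
is verifiable end to end.

## What it computes

For a scene image $I$ and its low-level saliency map $S$ (multi-scale
centre–surround or graph-activation backend over colour, intensity and
orientation channels), the scene is partitioned into four exhaustive ROIs:
hand-drawn *head* and *body* masks, and the remaining pixels split at the
8th decile of their saliency values into *lower*- and *higher*-saliency
areas, so that

$$\text{relative saliency}(R) \;=\; \frac{\overline{S}_{R}}{\overline{S}_{\text{scene}}}, \qquad
\sum_R \frac{A_R}{A_{\text{total}}}\,\text{relative saliency}(R) = 1 .$$

Gaze samples are parsed into saccades (velocity > 30°/s or acceleration
> 8000°/s², sustained ≥ 4 ms), fixations and blinks; fixations are
drift-corrected against the 300 ms pre-onset baseline (with recursive
±3 s.d. outlier removal over each participant's baselines, and exclusion of
trials with ≥ 20% blink time). Two headline statistics follow, per
participant, task and ROI:

* **area-normalized fixation frequency** at fixation index $k$:
  $F_{R,k} / \bar{A}_R$, the relative frequency that ROI $R$ received the
  $k$-th fixation divided by the ROI's mean pixel area;
* **first-entry latency**: the median over trials of the onset latency of
  the first fixation landing in $R$ (optionally conditional on $R$
  receiving the very first fixation).

Inference uses repeated-measures ANOVAs with Huynh–Feldt-corrected degrees
of freedom and partial $\eta^2$, Bonferroni-corrected paired t-tests with
$d_z$, Harrell–Davis shift functions with a pair-resampling percentile
bootstrap (1000 samples), and noncentral-t power analysis.

## Worked example

```r
library(scenegaze)

scn  <- generate_scene(random_scene_spec(seed = 3), seed = 3, scene_id = 1L)
sal  <- compute_saliency_map(scn)                 # centre-surround backend
part <- build_roi_partition(scn, sal)             # 8th-decile split
area_fractions(part)
#>   roi    area_px fraction
#> 1 head      3871   0.0126
#> 2 body     14438   0.0470
#> 3 lower   231113   0.752
#> 4 higher   57778   0.188

sapply(1:4, function(k) relative_roi_saliency(sal, part$labels == k))
#>   head   body  lower higher
#>   2.26   1.08   0.34   3.52
```

The generated distractor patches out-rank the social regions in relative
saliency (3.52 vs 2.26) while the lower-saliency background sits well below
average (0.34) — the stimulus property that lets social attention be
separated from physical saliency. Simulating and parsing one
social-detection trial:

```r
trial <- generate_gaze_trial(scn, part, behaviour_params(), "social_detection", seed = 11)
table(detect_events(trial$samples, geometry())$kind)
#> fixation  saccade
#>       35       34
```

A shift function comparing paired per-participant latency scores (condition
b − a at the Harrell–Davis quartiles, percentile bootstrap CIs from
resampling participants):

```r
set.seed(1)
fv <- rnorm(33, 277, 35)                 # free-viewing medians (ms)
sd_ <- fv - 20 + rnorm(33, 0, 12)        # detection: 20 ms faster
tidy(shift_function_dependent(fv, sd_, seed = 9))
#>       q est_a est_b difference ci_lower ci_upper p_boot
#> 1  0.25  264.  244.      -20.0    -24.4    -12.4      0
#> 2  0.50  286.  267.      -19.0    -24.3    -13.4      0
#> 3  0.75  303.  284.      -18.6    -24.1    -11.6      0
```

All three quartiles shift down by about 20 ms and every bootstrap CI
excludes zero: detection speeds first looks at heads across the whole
distribution, not just at its centre. `run_study(run_config(seed = 1))`
chains every stage — scene bank, saliency, ROIs, simulated participants,
event parsing, exclusion, scoring, ANOVAs, post-hoc contrasts and shift
functions — into one reproducible result bundle; `write_study_results()`
exports it as delimited text, and `read_run_config()`/`write_run_config()`
round-trip the full configuration through YAML.

Power planning for the paired design:

```r
required_n_paired_t(d_z = 0.50, power = 0.85, alpha = 0.05, alternative = "one.sided")
#> [1] 31
```

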