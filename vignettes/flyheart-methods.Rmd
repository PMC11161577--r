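---
title: "Quantifying Drosophila cardiac dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Drosophila cardiac dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flyheart)
```

## The problem

Semi-intact *Drosophila* heart preparations are filmed side-on with
high-speed bright-field microscopy (nominally 200 frames/s, ~400 x 300 px,
30 s per recording). The heart appears as a roughly horizontal tube; its
two walls oscillate vertically as the heart beats. Cardiac physiology is
read off the time course of the lumen diameter: diastolic and systolic
diameters (DD, SD), diastolic and systolic intervals (DI, SI), heart period
and rate (HP, HR), fractional shortening (FS), ejection fraction (EF),
arrhythmia index (AI), stroke volume and cardiac output (SV, CO), and
contractile latencies. Historically these are measured with semi-automatic
tools that need a human to mark wall positions; `flyheart` automates the
chain: segment the walls per frame with a small attention U-Net, average
the per-column lumen gap into a calibrated diameter trace, detect beats,
and derive the statistic suite — plus two downstream age classifiers.

Every stage is exercised against a seeded synthetic beating-heart
simulator, so the whole pipeline is testable without any recordings.

## The synthetic heart

`heart_spec()` describes a heart; `simulate_heart()` renders it. The
diameter waveform is a smoothed trapezoid per beat: a cosine-ramped
contraction from DD to SD, a systolic hold, a cosine-ramped relaxation, and
a diastolic plateau. We chose a trapezoid rather than a sinusoid so that
diastolic plateaus and systolic dips are unambiguous, mirroring observed
beating patterns; the ramp time is fixed at 10% of the heart period. The
systolic interval occupies `si_frac` of each period (default 0.4).

Per-beat heart periods are drawn from a normal distribution with mean
`hp_mean` and coefficient of variation `hp_cv`, truncated below at two
frame intervals so no beat degenerates; `hp_cv = 0` gives a metronomic
rhythm with exactly `duration / hp_mean` beats. Frames show two horizontal
wall bands of `wall_thickness` px whose inner-edge gap is
`round(diameter / pixel_size)` px, over a darker background, with additive
Gaussian intensity noise of standard deviation `noise_sigma` (default
0.05 on a [0, 1] intensity scale). The noise model is a stand-in — the
intensity statistics of real bright-field recordings are not characterized
here — so passing tests demonstrate correctness of the measurement chain,
not robustness to real microscopy artifacts (debris, pericardial cells,
drift, uneven illumination are deliberately not modeled).

`make_cohort()` builds labeled "young"/"old" cohorts by perturbing
diameters and mean period per heart (CV 5% by default). The default aged
phenotype follows the directional aging effects reported for the fly
heart: reduced FS (DD 55 / SD 44 um versus 60 / 40), longer and more
variable HP (0.7 s, CV 0.15 versus 0.4 s, CV 0.05). These are arguments,
not constants.

All randomness flows from one seed per object; sub-streams (waveform,
noise, cohort perturbations) are derived deterministically from it, so
identical seeds give bitwise-identical datasets.

## Segmentation

The segmenter is an attention U-Net operating on *temporal stacks*: the
network input for frame *t* is a three-channel image of frames
*t - 4*, *t*, *t + 4* (clamped at the clip edges so every frame gets an
output), encoding local wall motion. The encoder/decoder uses one
convolution per resolution level with filter counts 8, 16, 32, 64, 128 by
default and a rectangular 3 x 7 kernel — wider along the horizontal tube
axis, since the walls are horizontally extended structures. Skip
connections pass through additive attention gates: with decoder feature
`g` and encoder skip `x`, the gate computes
`psi = sigmoid(conv1x1(relu(conv1x1(g) + conv1x1(x))))` (the intermediate
width is half the level's filters) and forwards `x * psi` for
concatenation. The head is a single-channel 1 x 1 convolution with a
sigmoid, so the output is a per-pixel wall probability; the user picks a
threshold, and masks at a higher threshold nest inside masks at a lower
one.

Training minimizes soft Dice loss
`1 - (2 sum(p t) + eps) / (sum p + sum t + eps)` with Adam (step size
1e-3), a 16-image batch size, an 85/15 train/validation split, and keeps
the epoch checkpoint with the lowest validation loss. Frames are sampled
by diameter before training: frames are binned by their measured diameter
rounded to the nearest pixel, and up to 75 frames per bin are drawn without
replacement (all of a smaller bin), counteracting the diastole/systole
class imbalance; bins smaller than the cap are not resampled with
replacement, to avoid duplicate-image overfitting. Augmentation (random
horizontal flips and a small intensity offset) is on by default.

The network is implemented directly in R as a compact CPU engine:
convolutions gather kernel-offset blocks into a matrix and evaluate a
single BLAS multiplication; backward passes mirror the gathers as scatter
adds; gradients were verified against finite differences in the test
suite. This keeps the package self-contained and fully deterministic under
seed control. Scale is configuration: the tests and the acceptance script
train a 4-8-16-32-64 filter ladder on ~230 stacks of 32 x 48 px frames for
5 epochs (about two minutes on one CPU), which reaches held-out Dice
around 0.9 on the simulator; the default 8-128 ladder on full-size frames
is the configuration a GPU port would use.

## Diameter traces and M-mode

For each mask column, maximal vertical runs of wall pixels are found; with
at least two runs, the lumen is the count of non-wall rows strictly between
the uppermost run's last row and the lowermost run's first row. The
inner-edge-to-inner-edge convention is used because the masks label wall
tissue and DD/SD are chamber diameters; columns crossed by more than two
runs (speckle) use the outermost runs, and a column with fewer than two
runs carries no diameter. A frame's diameter is the mean of valid column
diameters in the user ROI, times the pixel size; a frame is invalid when
fewer than 25% of ROI columns are valid. Interior invalid gaps up to 5
frames are filled by linear interpolation between the nearest valid
neighbors; longer gaps and leading/trailing invalid frames stay flagged
and are excluded from beat analysis (interpolation never extrapolates).
Coordinates are 1-based in the R API, row 1 at top; ROI columns are
inclusive.

The M-mode image traces one pixel column (default: the ROI center — the
display column is an arbitrary choice) over time, tints wall pixels red,
and marks each DI start (end of relaxation) green and DI end (next
contraction onset) red.

## Beat detection and cardiac statistics

The beat detector is a velocity-threshold state machine (the published
pipelines leave the interval-detection algorithm to their code, so this is
this package's own documented construction, chosen to match the M-mode
annotation semantics of DI start/end):

1. smooth the trace with a centered moving average (default 5 frames);
2. differentiate by central differences, scaled to um/s;
3. a *contraction onset* is a downward crossing of `-v_thr`; a virtual
   zero velocity precedes the first frame, so a contraction in progress at
   the trace start is anchored there rather than dropped;
4. the *end of relaxation* is the first return of the velocity into
   `[-v_thr, +v_thr]` after the subsequent positive excursion;
5. DI runs from relaxation end to the next onset; HP is
   onset-to-next-onset (the onset-to-onset convention was chosen; peak-to-
   peak is the alternative and differs only by a phase);
6. the final onset without a successor is dropped (edge beats truncated by
   the recording are discarded from all statistics).

`v_thr` defaults to 20% of the 95th percentile of |velocity|, which scales
with the trace's own dynamics; a trace whose smoothed peak-to-peak
amplitude is below `min_amplitude_um` (default 1 um) reports no beats
rather than detecting noise. On noiseless piecewise-linear traces with the
smoothing window set to 1, detected boundaries sit within one frame of the
construction; the default 5-frame smoothing trades up to two frames of
boundary bias for robustness to pixel-quantization jitter (HP, a
difference of onsets, is unaffected by the common bias).

Per beat, DD is the largest diameter attained during the DI and SD the
smallest during the SI. Derived statistics use the conventions fixed here
(the source pipelines defer the formulas to prior literature):

* FS = 100 (DD - SD) / DD (%)
* EF = 100 (DD^2 - SD^2) / DD^2 (%) — fractional area change of a circular
  cross-section, the tube-heart proxy for ejected volume fraction
* AI = sd(HP) / median(HP), sample (n - 1) standard deviation, at least
  two beats
* SV = pi L ((DD/2)^2 - (SD/2)^2) / 1000 pL with L the ROI length in um
  (cylindrical tube model; 1 pL = 1000 um^3)
* CO = sum(SV) / sum(HP) (pL/s)
* HR = 1 / mean(HP)

Tachycardic events are beats with SI strictly over 0.5 s; bradycardic
events have DI strictly over 1.0 s (strict inequality, thresholds
configurable). Contractile latencies are measured on the velocity series:
time from onset to the most-negative sample, and from that sample to the
most-positive sample later in the same beat.

## Age classification

**Logistic pipeline.** Seven features per heart (DD, SD, FS, DI, SI, HP,
AI) feed a logistic model with unit-strength L2 regularization on features
standardized per training fold (ridge via `glmnet` with `lambda = 1/n`),
evaluated by stratified 5-fold cross-validation with per-fold accuracy,
AUROC and a pooled confusion matrix. None of the regularization choices
come from the source pipelines; they are documented defaults. For a model
linear on standardized features, Shapley attributions with a
mean-imputation value function have the closed form
`w_j (z_j - mean(z_bg_j))` on the log-odds scale; the package computes
this exactly, and the test suite checks it against brute-force enumeration
of all 2^7 feature coalitions (agreement to 1e-9, efficiency identity
exact).

**Video pipeline.** The per-frame sum of squared differences against frame
1 (`t0` is configurable; the reference frame choice is otherwise
arbitrary) is min-max normalized, binarized at 0.5, and decomposed into
maximal runs; the center frame (`floor((start + end) / 2)`, counting from
0) of each run — both low- and high-motion runs — is collected until 96
keyframes exist. Short videos repeat-pad the last keyframe with duration 0
and warn. The keyframes (downsampled to `frame_size`, default 96 x 128;
the tests use 16 x 16) pass through three convolution blocks of two 3 x 3
convolutions and a 2 x 2 max pool; the flattened features are concatenated
with the 95 inter-keyframe durations (in frames, standardized per training
fold; the frame rate is recorded alongside) and passed through three dense
layers to a sigmoid. Binary cross-entropy, Adam, stratified k-fold as
above. A probability of exactly 0.5 labels the sample "old" (documented
tie-break); reported log-likelihood is the log probability of the
predicted class.

Both classifiers are checked two-sided: they must separate the simulator's
aging cohorts well above chance, and sit at chance on permuted labels.
Because the synthetic cohorts are constructed to be separable (distinct
FS and HP distributions), these checks validate the training and
evaluation machinery — they say nothing about accuracy attainable on real
recordings.

## Numerical and design notes

* Problem sizes in the tests and acceptance script are deliberately small
  (32-48 px frames, a few hundred stacks, 5 training epochs, cohorts of
  40-100 per class) so a full run completes in minutes on one CPU; all are
  configuration, and the defaults mirror the full-scale setup.
* Dice loss uses a smoothing epsilon of 1e-7; Adam uses beta = (0.9,
  0.999), eps = 1e-8.
* The U-Net requires frame dimensions divisible by 2^(levels - 1); the
  simulator geometry in the tests is chosen accordingly.
* TIFF is the supported video container (multi-page, one page per frame);
  masks write as 0/255 pages. Traces, beat tables, statistics, events and
  CV reports write as plain CSV; configurations as YAML; CV summaries as
  JSON.
* Degenerate inputs fail loudly with typed messages: invalid specs name
  the violated bound, constant videos are rejected by the keyframe
  selector, thresholds outside [0, 1] are parameter errors, and empty beat
  tables propagate "insufficient data" errors rather than NaN statistics.

## Known limitations

* The simulator renders idealized two-band hearts; real recordings have
  occlusions, drift and texture the segmenter never sees here.
* Sub-pixel wall localization is out of scope; diameters are quantized to
  the pixel grid before calibration.
* AVI ingestion is not provided; recordings should be converted to
  multi-page TIFF.
* The published headline accuracies for age prediction on real fly
  recordings are not reproducible without those recordings; the package
  validates the machinery on synthetic cohorts instead.
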