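---
title: "Multimodal surgical gesture segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal surgical gesture segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

suturesegkit assigns one of four gesture classes — `entering`, `gripping`,
`passing`, `other` — to every frame of an open-surgery suturing video, from
three per-frame modalities: precomputed video embeddings, 6-DoF tool poses
(needle driver and tweezers), and two 21-joint hand poses. This vignette
documents the models, the tunable parameters, the numerical conventions, and
the design decisions taken where the methodology was genuinely open.

## Pose cleaning

Tool pose estimators for near-symmetric instruments intermittently return a
rotation composed with a symmetry element — a 180° flip about the tool's
y-axis, or simultaneous 180° flips about x and z, which is the same global
rotation. The default ambiguity group in `tool_symmetry_group()` is therefore
the order-two group {I, Ry(180°)}; a larger group can be supplied where the
upstream estimator's convention warrants it. `disambiguate_tool_rotations()`
walks detected frames in order and right-multiplies each rotation by the
symmetry element minimizing the geodesic angle
\(\theta = 2\arccos|\langle q_{t-1}, q_t s\rangle|\) to the previously
corrected frame. The greedy pass is linear-time; on smooth tracks corrupted
by independent flips it recovers the original sequence up to one global
symmetry element (a property the test suite checks over 100 seeded tracks,
and against exhaustive \(2^T\) minimization at small T).

Missing tool detections are filled by last-observation-carried-forward for
gaps of at most `max_gap_frames = 10` frames (1/3 s at 30 FPS); hand joints
use linear interpolation with the same gap limit, requiring a detection on
both sides. Boundary gaps are never filled. Imputed frames are flagged, and
the flattened features carry a per-tool / per-hand validity column (missing
frames are zero-filled with validity 0) so the temporal model can learn to
discount them; the flag can be dropped via `include_validity = FALSE`.

Both position and rotation tracks are then Savitzky-Golay filtered within
each contiguous observed span (window 9, order 2 by default: mild smoothing
that leaves gesture-scale dynamics at 30 FPS intact while reproducing
polynomials of degree ≤ 2 exactly). Quaternions are made sign-continuous,
filtered component-wise, and renormalized — avoiding Euler-angle
singularities. Spans shorter than the window pass through unchanged.

Training-time augmentations mirror common practice for this data: whole-video
180° flips about y and about x∘z (each with probability 0.5), Gaussian
position noise and small random-axis rotation perturbations (σ = 0.01 track
units / radians — magnitudes are not standardized in the field, so they are
configuration), and for hands one uniform rotation about the vertical axis
applied to all joints. All augmentations are rigid per video and seeded. The
cross-validation harness trains on fixed preprocessed features and does not
re-augment per epoch; the augmentation operations are provided (and tested)
for pipelines that precompute augmented copies.

## The temporal model

`build_mstcn_pp()` implements MS-TCN++: a prediction-generation stage of L
dual-dilated residual layers (layer *l* runs two kernel-3 convolutions with
dilations \(2^l\) and \(2^{L-1-l}\), concatenates them, and applies a 1×1
convolution, ReLU and residual add), followed by S − 1 refinement stages
that consume the previous stage's softmax probabilities through L kernel-3
dilated residual layers (dilation \(2^l\)). Every stage has a 1×1 output
head; the final stage is the prediction. The network is implemented in
RcppArmadillo with handwritten backpropagation and Adam, which keeps training
deterministic, dependency-free, and fast enough for full cross-validation
matrices on one CPU. Gradients are verified against central finite
differences in development.

Every stage contributes to the loss: frame-mean cross-entropy plus
\(\lambda\) times a truncated mean-squared difference of adjacent
log-probabilities, \(\min(\tau, |\log p_{t,c} - \log p_{t-1,c}|)^2\)
averaged over frames and classes, with the previous frame detached from the
gradient. The standard constants \(\lambda = 0.15\), \(\tau = 4\) are the
defaults; the term suppresses over-segmentation. Optimization is Adam
(default moments) with one full video per step, videos visited in a fixed
order; early stopping monitors mean validation frame accuracy with a
configurable patience and restores the best-validation parameters. Epoch
budgets and early stopping are not standardized for this architecture; the
package exposes both, and the test-suite experiments use 5–20 epochs with
patience 2–5 at learning rate 1e-3 — enough for convergence at the data
sizes below.

Long videos are subsampled at stride 2 (every 2nd frame) before training,
matching common practice for multi-thousand-frame operative video; metrics
are computed at the model's native stride, with `upsample_labels()` available
to map predictions back to the source frame rate. Optional input batch
normalization (`input_batchnorm = TRUE`) is off by default — multimodal
performance is typically higher without it.

The hyperparameter grids explored for this model family are L ∈ {3, 5, 8,
12}, S ∈ {2, 3, 5}, lr ∈ {1e-3, 1e-4, 1e-5}, with a hidden width
("feature size") of 128; the width default follows that convention, while
the experiment harness uses width 32 at desk scale.

## Fusion and ensembling

The straightforward multimodal route concatenates per-frame features
(`concat_modalities()`) and trains one model. The ensemble route trains one
model per modality plus the concatenated model and averages their **logits**
per frame (`average_logits()`). Logits are averaged rather than softmax
probabilities because a confident model produces large-norm logits and
should dominate the vote; `logit_norm_accuracy_bins()` makes this concrete
by sorting frames into equal-sized norm bins (remainder to the lowest bins)
and reporting per-bin accuracy, and `ensemble_delta_bins()` shows where in
confidence space the ensemble helps. Argmax ties break toward the lowest
class index.

Averaging can introduce single-frame flicker, so `smooth_predictions()`
iteratively replaces interior runs shorter than `min_run` (default 3 frames
≈ 100 ms at 30 FPS) with the label of the longer adjacent run, ties to the
left; boundary runs are exempt because they lack a two-sided neighbourhood.
The exact neighbour rule is not standardized, so `min_run` is exposed.

## Evaluation

Frame accuracy and macro-F1 are computed frame-wise ('other' is a regular
class, not background). The segmental edit score is
\(100\,(1 - \mathrm{Lev}(\hat{s}, s)/\max(|\hat{s}|, |s|))\) on the
segment-class strings, floored at 0. Overlap F1@k pools segments of all
classes; each predicted segment, in temporal order, matches the unmatched
same-class ground-truth segment of maximal interval IoU and is a true
positive when IoU ≥ k (k = 0.10, 0.25, 0.50). Both segmental metrics are
validated against independent brute-force oracles on a thousand random
sequence pairs.

Cross-validation is leave-one-user-out over ordered surgeon pairs: each fold
holds one surgeon's videos out for validation and another's for testing, so
n surgeons give n(n−1) folds (20 for five). Reported values are mean ± sd
across folds (sample sd by default; population available), a fold's value
being the unweighted mean over its test videos. Paired comparisons use the
Wilcoxon signed-rank test with one pair per (video, fold with that video in
test); zeros are dropped, midranks handle ties, the null is enumerated
exactly for n ≤ 20 without ties and approximated normally with tie
correction otherwise. One-sided "greater" suits superiority hypotheses
(ensemble beats single modality); "two_sided" suits difference hypotheses.

## The synthetic operating-room simulator

No public dataset carries this exact structure, so `simulate_dataset()`
generates one with the printed statistics of the target domain: repeated
suturing cycles entering → gripping → passing with an `other` segment after
30% of cycles (reproducing the ~259 'other' per ~850 cycles ratio), and
negative-binomial segment durations with class means 138 / 41 / 66 / 259
frames at 30 FPS (dispersion is a free parameter, default size 5, since only
means are published). Five surgeons × three videos of nine cycles
(~3,000 frames) is the default scale. Per surgeon, additive style offsets in
trajectory and feature space make leave-one-user-out folds genuinely harder
than random splits; per modality, noise is drawn independently so ensemble
members make complementary errors.

Tools follow class-specific smooth position templates with a
phase-parameterized wobble and an exponentially smoothed class-conditioned
rotation path; frames are flip-corrupted with probability `flip_rate` and
detection gaps of geometric length are inserted at the dropout rate. Hands
ride their tool's template with a class-dependent articulation scale on a
fixed 21-joint template. Video embeddings are class prototypes plus style
plus temporally smoothed noise.

A single `snr` knob scales all modality noises. The per-modality noise
scales (video 0.5·√D/snr, tool positions 2.0/snr, rotations 0.8/snr, hand
joints 1.2/snr) and the style magnitude (0.25) were calibrated once so that
at low snr the three single-modality models land in a comparable accuracy
band with the ensemble on top — the qualitative regime reported for real
multimodal gesture recognition — rather than one modality dominating;
they are fixed defaults, not fitting knobs. snr = 8 and snr = 1 serve as
the high- and low-noise endpoints in the test suite, following the snr grid
{8, 4, 2, 1} used for the feature-degradation checks.

What the simulator does **not** emulate: photorealistic appearance, camera
and lighting variation beyond additive style offsets, biomechanically valid
hand kinematics, annotation noise, and correlated cross-modality failures
(e.g. occlusions hitting tools and hands together). Passing tests therefore
demonstrate that the pipeline's machinery is correct and that its relative
comparisons behave as designed — not that real operating-room performance
would match the simulated numbers.

## Numerical conventions and degenerate inputs

* Frame indices are 0-based on disk; class ids are 1-based in R. Event and
  segment intervals are half-open (`[start, stop)`).
* Quaternions are scalar-first, right-handed; readers renormalize valid
  quaternions and reject degenerate ones (a strict unit-norm tolerance is
  opt-in).
* Geodesic tie-breaks in disambiguation keep the earlier symmetry element;
  argmax tie-breaks take the lowest class index.
* The truncated-MSE term is skipped for single-frame sequences; log-softmax
  uses max-shifting for stability; batch normalization guards zero variance
  with ε = 1e-5.
* Training aborts with a diagnostic on non-finite loss; weight
  initialization is He-style, deterministic given the config seed.
* Problem sizes in the test suite were chosen for single-CPU runs: width-32
  models at stride 2 on ~3,000-frame videos, 20-fold matrices, and five
  simulator seeds for the stochastic ensemble comparison.

## Known limitations

* The compiled training loop covers MS-TCN++ only; alternative temporal
  models can implement the same `predict_logits()` contract but no second
  architecture ships with the package.
* Hyperparameter grid search is out of scope by default; the harness keeps
  one configuration per modality combination across folds.
* Per-epoch re-augmentation is not wired into the training loop (see above).
* The exact neighbour-smoothing rule, Savitzky-Golay parameters, noise
  magnitudes, and ensemble membership per modality combination are
  field-informed defaults rather than published constants; all are exposed
  in configuration objects.
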