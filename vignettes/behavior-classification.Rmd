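---
title: "Classifying bird behavior from markerless pose tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bird behavior from markerless pose tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poseclass)
```

## The problem

Markerless pose estimators such as DeepLabCut turn a video of an animal
into a multivariate time series: for every frame, an x/y image coordinate
and a tracking confidence ("likelihood") per tracked body part. For a
pigeon filmed from a single camera this is typically ten keypoints — head,
beak, left and right neck, body center, four wing points and the tail —
sampled at high frame rates (a 10-minute recording at 119.88 fps is
`expected_frame_count(600, 119.88)` = 71,928 frames, each reduced from a
raw image to `reduced_bits_per_frame(10, 2, 32)` = 640 bits of keypoint
data). Ethologists want frame-level behavior categories out of this
stream: eating, standing, walking, head shaking, tail shaking, preening,
fluffing. poseclass implements the full path from pose CSV to ethogram.

## Egocentric normalization

Behavior is a property of the body configuration, not of where the bird
stands in the image. Each frame is therefore normalized independently:

1. **Translation.** The displacement vector $s = (-x_\text{body},
   -y_\text{body})$ is added to every keypoint, placing the body center at
   the origin.
2. **Rotation.** A synthetic *middle neck* vector $v = v_\text{left neck} -
   v_\text{right neck}$ defines the heading. The angle
   $\theta = \operatorname{atan2}(v_x, v_y) \cdot 180/\pi$ — the signed
   angle of $v$ measured from the positive y axis — is removed by applying
   the counter-clockwise rotation matrix
   $R = \begin{pmatrix}\cos\theta & -\sin\theta\\ \sin\theta &
   \cos\theta\end{pmatrix}$ to all keypoints, which maps $v$ onto the
   non-negative y axis.

The composite is a rigid motion, so all within-frame geometry (pairwise
inter-part distances) is preserved to numerical precision, the transform
is idempotent, and two tracks differing only by a global rotation plus
shift normalize identically. These three properties are tested as
invariants rather than on single examples.

Two definitional choices deserve a note. The heading could plausibly be
defined by the *midpoint* of the two neck points (a body-to-neck "spine"
direction) instead of their difference; both remove global heading, and
the difference form is the default with the midpoint exposed as
`middle_neck_mode = "midpoint"` for users who prefer a spine-aligned
frame. Second, a frame where the two neck points coincide has no defined
heading; such frames are left unrotated (angle 0), flagged in the returned
state, and never dropped — dropping them would desynchronize the track
from its frame-range labels.

Normalization is strictly per-frame. No temporal smoothing or kinematic
filtering is applied; pose-estimator output is used as-is.

## Labels, features and windows

Behavior annotations arrive as inclusive frame ranges (0-based
`start_frame`, `end_frame`, `behavior`). Before use they are validated:
names must match the vocabulary byte-for-byte (near-misses differing only
in case or surrounding whitespace are reported separately from unknown
names), slices must not overlap — overlap is an error, not
last-writer-wins, because exclusive behavior categories make silent
override an annotation bug — and no slice may extend past the track.
Frames covered by no slice are removed, with original indices retained.

Keypoints whose mean likelihood falls below a cutoff (default 0.6, the
usual pose-estimation prediction cutoff) are excluded wholesale; for a
pigeon this typically removes the frequently self-occluded beak, leaving
9 parts × 2 coordinates = 18 features per frame. The remaining per-frame
features are segmented by a sliding window of `window_size` frames with
step 1, each window flattened time-major into a vector of length
$n_\text{features} \times \text{window\_size}$. Training windows never
straddle a label boundary or a gap left by unlabeled-frame removal —
mixed-label supervision would be incoherent. Each window is attributed to
its **last** frame (causal anchoring): a prediction refers to the moment
its window ends, which keeps ethograms usable in on-line settings. The
attribution convention matters only at behavior transitions, at most
`window_size - 1` frames per bout.

## The classifier

The core fit is `behavior_classifier()`: a random forest over window
vectors, with

* `mtry = floor(sqrt(p))` candidate features per split, `p` the flattened
  vector length (the square-root rule);
* **balanced class weights** $w_c = \dfrac{\text{total}}{n_\text{classes}
  \cdot \text{count}_c}$, so each behavior contributes equal total weight
  regardless of frequency — rare, brief comfort behaviors would otherwise
  be swamped by the common postural classes. The weights satisfy
  $\sum_c w_c \, \text{count}_c = \text{total}$ exactly, which is tested
  numerically;
* 20 trees by default — validation curves over 1–100 trees show the usual
  rise-then-plateau, and 20 is a good accuracy/time tradeoff;
* a fixed integer seed and single-threaded fitting, so a refit reproduces
  bit-identical predictions.

The forest is fit by `ranger` behind a minimal backend contract
(`fit(x, y, weights, config, seed)` / `predict_proba(fit, x)`), so deep
time-series backends can be registered later without touching the
pipeline; only the random forest ships. Tree-level hyperparameters not set
here (node size, depth) stay at library defaults and are recorded in the
model object.

`predict_proba()` returns one probability vector per window (rows sum
to 1), attributed to the window's anchor frame.

## Evaluation

Per-class precision, recall and F1 use the standard ratios with a
conservative zero convention: any metric whose denominator is zero is 0.
The overall score is the support-weighted F1
$\frac{1}{N}\sum_i F1_i \cdot \text{support}_i$, with supports taken from
the true labels (a class absent from a test fold simply contributes zero
support).

Cross-validation is five-fold and **non-shuffled**: windows are cut into
five contiguous blocks (remainder to the last), fold $i$ tests on block
$i$. Consecutive frames of high-fps video are nearly identical, so
shuffled folds would leak test information into training and report
unrealistically good scores. The last fold — train on the first ~80%,
test on the last ~20% — is kept in full (predictions, probabilities,
confusion matrices) for per-class reporting. Learning curves subset each
fold's training block by contiguous *prefixes*, never random subsamples,
preserving the same discipline.

## Post-processing: tuple thresholds

The default decision rule is the argmax of the probability vector, ties
broken to the first class in class order and flagged. On top of it,
*tuple thresholds* generalize binary decision-threshold tuning to
multi-class output: a tuple `(fallback, target): threshold` reassigns a
frame predicted as `target` to `fallback` whenever the fallback's
probability is at least the threshold. Tuples apply in list order, first
match wins, at most one reassignment per frame. The rule compares the
fallback's *probability* to the threshold (not the target–fallback
margin); both formulations trade target recall for precision, and the
probability form is simpler to reason about: at threshold 0 every target
frame is reassigned, at an unreachable threshold the operation is the
identity, and the target-class prediction count is monotone in the
threshold — all tested as properties. Choosing tuples is deliberately
left to the user; the package provides no automatic threshold
optimization.

## The synthetic benchmark

The simulator exists so that every stage is testable without recordings.
It renders a 10-keypoint top-down pigeon silhouette (1280 × 960 canvas,
119.88 fps) through seven behavior regimes:

| behavior | kinematics |
|---|---|
| standing | static template; head slowly sweeps ±10 px ("looking around", period 80–160 frames) |
| walking | distinct gait posture translated at 3 px/frame along a heading |
| eating | head and beak lowered, periodic dips (period 30) |
| head_shake | fast lateral head/beak sinusoid, amplitude 25 px, period 8 |
| tail_shake | fast lateral tail sinusoid, amplitude 30 px, period 12 |
| preening | beak and head held at the left wing with slow contact episodes |
| fluffing | wing points extended 1.4× with amplified jitter |

All keypoints carry i.i.d. Gaussian jitter (default SD 2.5 px, the
magnitude of typical pose-estimator error), likelihoods sit at 0.95
except the beak, which is occluded on 60% of frames (likelihood 0.1), so
default feature selection excludes it — as it should. Everything is
deterministic given the seed.

The default benchmark (`make_benchmark()`) interleaves bouts with a
skewed profile — standing 40%, eating 25%, walking 15%, preening 10%,
fluffing 6%, head and tail shake 2% each — with shakes in 24–48-frame
bursts and other bouts of 80–240 frames, each bout placed at a random
position and heading. The design encodes the statistical structure that
matters for the classifier, not anatomical realism:

* *postural* classes are separable from single frames;
* *oscillatory* classes overlap the standing posture in any single frame
  (the slow look-around sweep occupies the same lateral range as a
  mid-swing shake) but are unambiguous across a 16-frame window, which is
  the mechanism behind the window-size effect the evaluation reproduces;
* rare classes stress the balanced weighting;
* walking demonstrates that egocentric normalization removes locomotion:
  with zero noise a walking bout normalizes to a constant posture.

What the simulator does **not** emulate: tracking glitches and identity
swaps, likelihood-correlated coordinate error, smooth behavior
transitions, inter-individual variation, or any interaction with a real
feeder. Green tests on synthetic data therefore demonstrate the
correctness of the machinery and the qualitative mechanisms, not field
performance on real birds.

## Problem sizes and numerical choices

The bundled evaluation runs on a 50,000-frame benchmark (about 45,000
16-frame windows of 288 features), five-fold CV with 20 trees — a single
CPU handles it in a couple of minutes. Tolerances: orthonormality and
isometry to 1e-9; the normalization output contract (body at origin,
neck axis on +y) and its invariances to 1e-6, reflecting accumulated
trigonometric rounding; probability rows sum to 1 within 1e-9. Angles are
stored in degrees in `(-180, 180]`; internal trigonometry uses radians.

## Limitations

* Only the random-forest backend ships; convolutional time-series
  backends plug into the backend contract but are not implemented.
* Raw coordinates are the only features — no velocities, angles or other
  engineered kinematics — and step sizes other than 1 are unsupported.
* Post-processing covers argmax and tuple thresholds; no sequence-level
  smoothing (HMMs, median filters) is applied.
* Rendering predictions onto video is out of scope; the SRT overlay
  manifest is the hand-off point to external players.
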