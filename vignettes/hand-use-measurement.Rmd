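---
title: "Measuring functional hand use from egocentric video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring functional hand use from egocentric video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egohanduse)
```

## The measurement problem

After a cervical spinal cord injury, recovery of hand function is the top
rehabilitation priority, yet almost all upper-extremity outcome measures are
administered in the clinic and say little about how much a person actually
uses their hands at home. A head-mounted first-person camera offers a direct
window: the wearer's own hands and workspace are in view during activities
of daily living. `egohanduse` implements a complete analysis chain that
turns such footage into three interpretable outcome measures per hand:

* the percentage of recording time spent in hand–object interaction,
* the mean duration of individual interactions (seconds), and
* the number of interactions per hour.

An *interaction* means the hand is manipulating an object for a functional
purpose; a hand resting on an object, or waving through the air, does not
count. The pipeline makes one binary interaction decision per video frame
and per hand, then aggregates the decisions into per-hand timelines and
metrics.

## Pipeline stages and their models

Video is analysed at a reduced resolution (height 480 px by default, aspect
preserved, width rounded to the nearest even integer); higher resolution
adds cost but no accuracy for this task. Frames are indexed from 0 and
timestamped `index / fps`, with 30 fps assumed when the container does not
record a rate.

### Hand detection

Detection is a pluggable contract: anything that produces per-frame boxes
with scores can drive the pipeline, including boxes exported from a
convolutional detector (`load_external_detections()`). The built-in baseline
(`detect_hands()`) thresholds a skin-colour back-projection at 0.75 of its
maximum, keeps connected components covering at least 0.1% of the frame, and
returns their tight boxes scored by mean skin probability (at most 4 per
frame by default). Boxes touching the frame border are kept, since
egocentric hands usually enter from a border.

### Arm angle: verification and handedness

Every candidate box is checked with a rotating three-rectangle Haar-like
feature (`arm_angle_feature()`). At each 1° step, a centre rectangle runs
from the box centroid to the image border; two parallel rectangles of the
same width flank it. The response is the mean difference in the coefficient
of variation (CV = SD/mean of intensity) between the side rectangles and the
centre one: a bare forearm is a smooth, low-CV region against cluttered
surroundings, so the response peaks when the centre rectangle lies along the
arm. The 360 raw responses are summed into 72 five-degree bins; binning is a
partition, so the binned vector conserves the raw profile's total.

The angle convention is: 0° points image-left, angles increase clockwise on
screen, hence 90° is up, 180° right, 270° down. This is the unique
convention in which the quadrant rule reads naturally: the top half (0–180°)
corresponds to an arm reaching down into the view from above — someone
else's hand; 180–270° (bottom-right) is the user's right arm; 270–360°
(bottom-left) the user's left arm. `classify_handedness()` applies exactly
that rule to the quadrant sums, with ties resolved right, then left, then
other. A 150-tree random forest over the 72 bins (`train_hand_verifier()`)
confirms that the box actually contains a hand before it proceeds.

Two geometric choices were open and are fixed as follows: the rectangle
width is half the shorter box side (`arm.rect_width_frac = 0.5`), and the
response sign is side-minus-centre so that an aligned smooth arm yields a
large *positive* response. A rectangle with fewer than 4 pixels or
near-zero mean intensity contributes CV = 0, which keeps the feature finite
at frame borders.

### Hand segmentation

Within a verified box, `segment_hand()` combines two cues. Skin colour: the
frame is back-projected through a chroma histogram (normalized-rg) derived
from a two-component Gaussian-mixture skin model and thresholded at 0.75 of
the maximum. Edges: the default operator (`edge_gradient_nms()`) takes the
gradient of the Gaussian-smoothed image (σ = 1.5 px) and thins it by
non-maximum suppression, yielding thin contour-like edges; the strength map
is binarized at 0.05 of its maximum and morphologically closed (3×3 square,
dilate then erode). Both thresholds were chosen empirically for this kind of
system and may need revisiting for a different camera; they are exposed as
`seg.skin_thresh` and `seg.edge_thresh`.

The dilated edge map is subtracted from the skin mask, splitting regions
that skin colour alone would merge. Candidate contours (connected
components) inside the box are filtered: filled area must be between 2% and
75% of the box area, and contours whose perimeter lies between 90% and 110%
of the box perimeter are discarded as box-hugging artefacts. The winner is
the contour whose filled area has the greatest fractional overlap with the
dilated edge map (larger area wins ties). Because the edge subtraction
removes a one-element ring from every candidate's boundary, the winning
mask is dilated once by the same 3×3 element before use — without this the
mask is systematically one ring too small.

The box is then re-centred at the midpoint of the winning contour's
centroid and topmost pixel, keeping its size (clamped to the frame). In an
egocentric view the arm hangs below the hand, so this midpoint pulls the box
up onto the hand; the re-centred box can never move down when the top pixel
is above the centroid. Frames where no contour survives return nothing — a
segmentation failure that the timeline layer later treats as a missing
frame.

### Interaction features (122 values)

Three feature families describe each re-centred box, computed over three
regions: the segmented hand, the box, and the background (frame minus box).

*Motion (60).* Dense optical flow between the previous and current frame is
summarized per region into 15-bin L1-normalized histograms of magnitude
(0–20 px, overflow in the top bin) and direction (full circle). The feature
is two difference vectors — hand-minus-box and background-minus-box — on
the premise that a held object moves with the hand while an untouched one
moves with the background. The flow estimator is a pyramidal iterative
Lucas–Kanade scheme (3 levels, 3 iterations per level, Gaussian window
σ = 2 px, Tikhonov regularization 1e-4) implemented in compiled code; it
was chosen over polynomial-expansion methods for robustness at the small
displacements involved and is exact enough to recover a 3-px translation to
within half a pixel in the median.

*Shape (60).* The box crop is resized to 10% of the frame height by 15% of
the frame width — guaranteeing identical dimensions regardless of box size
— and described by a histogram of oriented gradients (9 unsigned
orientation bins, 8×8-px cells, 2×2-cell blocks, L2 block normalization).
PCA, fitted on training data only, reduces the raw descriptor to 60
components so the shape block matches the motion block's size. For very
small frames the block size degrades gracefully to the available cells.

*Colour (2).* HSV histograms (15 bins per channel, concatenated,
L1-normalized) are compared with the Bhattacharyya distance
`sqrt(1 − Σ sqrt(p q))`: box vs hand and box vs background. Objects near the
hand that differ in colour from both push these scores up.

The blocks concatenate to the 122-value combined feature
(`assemble_feature()`): motion, then shape, then colour.

### Classification and evaluation

A 150-tree random forest (`train_interaction_model()`, fixed seed, default
`sqrt(p)` features per split, unlimited depth) makes the per-frame binary
decision at the 0.5 vote threshold. Left- and right-hand frames are pooled
into one classifier; timelines are split by handedness afterwards.

`evaluate_loso()` implements leave-one-subject-out cross-validation: for
each held-out subject, both the shape PCA and the forest are refitted on the
remaining subjects, so no test-subject information can leak into either
fit (the fold bookkeeping is kept on the result object and asserted in the
tests). Scores are per-subject, per-hand F1 and accuracy with means ± SD.
`ablate_family()` reruns the protocol with a single feature family.

### Timelines and functional measures

Per-frame decisions are merged into per-hand timelines
(`build_timeline()`). A hand that disappears immediately after an
interaction keeps its interaction state for up to 90 frames (3 s at
30 fps) — detection and segmentation failures should not split one
manipulation into several. Absence after a *no-interaction* frame is never
bridged: the rule prolongs interactions only. Longer absences, and frames
never seen, become no-interaction.

The binary timeline is then smoothed with a 120-frame (4 s) equally
weighted centred moving average (edge windows shrink to the available
frames), min–max normalized over the whole recording, and thresholded at
0.5 (`smooth_threshold()`). A constant signal bypasses normalization —
all-zero stays zero, all-one stays one — avoiding a 0/0. Smoothing
suppresses single-frame flicker and brings out task-scale structure; the
same filter must be applied to manually labelled timelines before any
comparison, so predicted and reference metrics are computed from
identically treated sequences.

`extract_metrics()` reads maximal runs of the smoothed sequence as
individual interactions. By construction the three measures satisfy
`pct = n × mean_duration / total_time × 100` exactly whenever at least one
interaction exists; with none, duration and rate are undefined and are
reported as `NA` (JSON `null`).

`validate_metrics()` correlates predicted and reference metrics across
subjects: Shapiro–Wilk at α = 0.05 on both vectors selects Pearson (both
normal) or Spearman, and the null of no correlation is tested one-tailed
(right), significance at p = 0.05. The Shapiro–Wilk choice is the package's
own; any reasonable normality screen would serve.

## The synthetic-scene generator

Every learned or tuned stage is exercised against generated scenes with
exact ground truth (`generate_scene()`): a skin-coloured elliptical hand
with an arm strip running to a frame border, over a static noise-textured
background, with an object that rigidly follows the hand (interaction),
moves independently, or is absent (both no interaction). Co-motion is the
operational definition of interaction here — the minimal mechanism that
gives the motion features the same signal structure they face in real
footage.

Deliberate design choices, fixed before any evaluation and kept since:

* Skin pixels share one chroma, placed at the mode of the baseline skin
  model, and vary only in luminance (±3%): hands are smooth, shaded
  regions. Backgrounds carry independent per-pixel RGB noise (SD 0.08):
  cluttered texture. This contrast — smooth arm against busy background —
  is exactly what the CV-based arm feature and the edge operator assume.
* Background luminance roughly matches skin luminance, so figure–ground
  contrast lives mostly in chroma. A large luminance gap would make the
  centre Haar rectangle bimodal at every angle and swamp the quadrant sums
  with a constant bias.
* The arm strip is slightly wider (1.5 × the hand's vertical semi-axis)
  than the Haar centre rectangle, so a perfectly aligned rectangle sees
  pure arm.
* The "hand box" ground truth pads the ellipse's tight box by 18% per
  side, mimicking a detector's looser box; a tight ellipse box would fill
  ~79% of itself and trip the 75% contour-area filter by construction.
* Scene synthesis and subject assembly are fully seeded; identical seeds
  give byte-identical frames and manifests.

`generate_subjects()` assembles leave-one-subject-out datasets: each
subject is a sequence of 60-frame segments, sides balanced left/right and
interaction segments allocated to hit the target positive rate (48% by
default, the class balance typical of an ADL session) as closely as the
segment grid allows; subjects differ in trajectories, sizes, speeds and
object colours. Features for these datasets are extracted against the
ground-truth masks and boxes, isolating what the classifier can do from
what the detector gets wrong. The end-to-end pipeline is trained and
evaluated separately, with features flowing through its own detection and
segmentation (`fit_pipeline_models()`), precisely because those two
regimes differ.

What the generator does *not* emulate: camera egomotion (backgrounds are
static), lighting changes and glare, motion blur, skin-coloured distractor
objects such as wood, occlusion by other people's hands, and real hand
articulation (the hand is a rigid ellipse). Passing tests on these scenes
therefore demonstrates that the algorithms are implemented correctly and
behave as designed under their own assumptions — not that real-world
accuracy will match; on real recordings of daily activities, published
systems of this design reach F1 scores around 0.7, not the near-perfect
scores seen on clean synthetic scenes.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use scenes of 160 × 284 or
similar, 1–3-frame scenes for geometry checks, 200 frames for segmentation
quality, five 600-frame subjects for cross-validation, and 1000 Monte-Carlo
replicates for the size of the validation test; these sizes give stable
rates while keeping a full run comfortable on one CPU. The analysis path
itself is resolution-independent and defaults to 480p.

Degenerate inputs are pinned down explicitly: CV of a near-empty rectangle
is 0; empty regions yield all-zero histograms; a constant timeline bypasses
min–max normalization; an all-negative run list leaves duration and rate
undefined rather than zero; a constant metric vector is a validation error
(correlation undefined). Ties are deterministic everywhere (handedness
right > left > other; contour selection by larger area; detection by score
then area), which is what makes end-to-end runs byte-reproducible.

## Known limitations

* The baseline detector is colour-based and will fire on any skin-chroma
  region; it stands in for a trained detector behind the same contract and
  is the component to replace first on real data.
* One decision per hand per frame: when two boxes claim the same hand,
  only the higher-scored one survives; overlapping hands are not
  disambiguated.
* Handedness is decided per frame from the arm angle alone, with no
  temporal smoothing of identity; brief misassignments are left to the
  timeline filter.
* The moving-average window (120 frames) sets the temporal resolution of
  the metrics: interactions much shorter than ~2 s are smoothed away by
  design.
* Correlation-based validation needs several subjects (≥ 3, realistically
  many more) and non-constant metric vectors.
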