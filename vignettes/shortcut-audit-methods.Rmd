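---
title: "Auditing and mitigating demographic shortcut learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and mitigating demographic shortcut learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairaug)
```

## The problem this package addresses

Deep image classifiers trained on medical images can recover a patient's
race, age band or sex from the image alone — often more easily than they
detect the pathology they were built for. When demographic attributes are
also correlated with label prevalence (as they are in real radiology
cohorts), an easily learnable demographic cue becomes a *shortcut*: the
model leans on it instead of the clinical signal, and its performance then
differs systematically across demographic groups.

`fairaug` implements an audit-and-mitigate workflow around one mitigation
idea: if the shortcut feature is geometrically fragile (like a technician's
metal marker in the corner of a radiograph) while the clinical signal is
geometrically robust, then *stochastic geometric distortion* of the
training (or test) images destroys the shortcut without destroying the
task. The package provides:

1. a synthetic cohort generator that plants a controllable demographic
   shortcut alongside a geometry-robust disease signal;
2. the four-operator distortion family (rotation, shear, scaling, fisheye)
   with chest-radiograph and brain-MRI presets;
3. an architecture-agnostic training harness with a CPU-scale reference
   CNN, weighted-F1 threshold selection, and test-time augmentation;
4. the audit statistics: association tests, demographic classifiability,
   grouped fairness gaps with bootstrap intervals, and a task-transfer
   probe of the learned representation;
5. comparison debiasing methods (balanced subsampling, stratified models,
   adversarial gradient reversal, distribution matching, an
   augmented-Lagrangian risk equaliser) that plug into the same harness;
6. gradient-based interpretation (Grad-CAM, integrated gradients, mean
   saliency maps, discordant-case selection).

## The synthetic cohort: what it emulates and what it does not

`cohort_spec()` describes a subject-grouped cohort. Each subject belongs
to one categorical group (the race / age-bin / sex stand-in), drawn from
the spec's proportions; each of its images carries binary labels drawn
from the group's prevalence row `pi[g, l]`, so the group–label dependence
found in real radiology cohorts is reproduced by construction. Images are
floating-point in [0, 1] on a constant background of 0.3 (the scale of a
histogram-equalised grayscale radiograph) with:

* a **disease signal**: a round blob of positive contrast (default
  contrast 0.045, radius 6 at 64×64) placed near the image centre with
  small jitter. A central blob survives every operator in the distortion family
  — rotation and shear move it little, shrinking keeps it visible, the
  fisheye warp deforms but does not erase it;
* a **shortcut**: by default a `corner_token` — a bright square whose
  corner is a deterministic function of the group — carried by a subject
  with probability `leak_rate` (1 by default, a fully deterministic
  shortcut). The token realises the "corner marker" hypothesis and is
  exactly the kind of feature the distortion family destroys: a ±90°
  rotation relocates it, shrinking pulls it inward, the fisheye bends it.
  `border_marker` and `global_offset` variants are provided; which image
  features encode demographics in real radiographs is unknown, and these
  three are stand-ins, not claims about the real mechanism;
* Gaussian pixel noise (default sd 0.08), redrawn per image, while the
  group and the shortcut realisation are shared at the subject level —
  this is what makes subject-wise splitting consequential.

Intensities are quantised to the 16-bit grid at render time so that
saving a cohort (16-bit TIFF in 2D, NIfTI in 3D) and loading it back is
bit-exact.

Default study conditions: 300 subjects, one image each, three groups at
proportions (0.2, 0.3, 0.5), one label at per-group prevalence
(0.2, 0.5, 0.8), token strength 0.35 over a 0.3 background with noise
0.08. The strong label–group coupling is deliberate: a shortcut is only
worth exploiting when the group carries real information about the
label, and only then does a label detector embed demographic features
for the task-transfer probe to find. The flip side is worth
understanding: because the corner token (at `leak_rate = 1`) encodes
*group membership only*, the most a detector can extract from it is the
group's prevalence prior. Removing a correct prior by augmentation
therefore does not shrink — and can widen — the spread of per-group
error rates, a behaviour that differs from disparity reductions
observed on real cohorts, where shortcut features plausibly modulate
per-group discrimination rather than just the prior. Modelling that
would need a label-linked shortcut (e.g. a marker whose association
with the finding varies by group), which `shortcut_spec()` deliberately
does not claim to capture. These give a strong but not saturated shortcut: a linear classifier
on raw pixels recovers the group at AUC > 0.9, and chance when
`leak_rate = 0`. The disease contrast (0.045) was calibrated once so
that desk-scale label detection lands near AUC 0.83 — clearly harder
than recovering the group, the regime in which shortcut exploitation is
worth auditing — rather than saturating at 1, where error-rate
disparities degenerate to zero. The generator does **not** attempt photorealism, scanner
or site effects, DICOM metadata, or continuous age — the age-like
attribute is categorical, mirroring the binned ages used in cohort
tables. Consequently, a passing audit here shows the *machinery* is
correct and the mitigation works against geometric shortcuts of this
kind; it does not show that real demographic encodings in radiographs are
geometrically fragile.

## The distortion family

All operators are inverse-mapped warps with bilinear (2D) or trilinear
(3D) interpolation for images and nearest-neighbour for masks, fill value
0 outside the frame, shape preserved, and output clamped to [0, 1].
Identity parameters (0°, 0 rad, factor 1, k = 0) reproduce the input
bit-exactly.

| operator | parameter | CXR preset | MRI preset |
|---|---|---|---|
| rotation | angle (degrees) | [-90, 90] | [-10, 10] |
| shear | angle (radians) | [-pi/4, pi/4] | [-pi/6, pi/6] |
| scaling | factor | [0.4, 1] | [0.8, 1] |
| fisheye | coefficient k | 0.4 | 0.4 |

Numerical choices worth stating:

* **Shear convention.** The source recipe gives shear parameters in
  radians without fixing the convention; here the parameter is an angle
  and the displacement factor is `tan(radian)` along the column axis,
  anchored at the image centre (`|radian| < pi/2`). Shearing by `-radian`
  inverts the map exactly up to interpolation.
* **Fisheye model.** With radii normalised so the corner farthest from
  the (uniformly drawn) centre sits at radius 1, the output point at
  radius r samples the input at `r (1 + k r^2) / (1 + k)`. This is the
  identity at k = 0, fixes the centre, is strictly monotone in r, and is
  the identity again at the normalisation radius, so its displacement
  peaks at `r = 1/sqrt(3)`. The exact parameterisation used by the
  original fisheye reference is not published; this barrel model is
  documented as swappable.
* **Composition.** The default `single_random` mode draws one of the four
  methods uniformly per image (matching a one-distortion-per-image
  augmentation table); `compose_all` chains all four in the fixed order
  rotate, shear, scale, fisheye. Train-time augmentation re-samples every
  epoch rather than fixing one distorted copy of the dataset — the
  stronger and more common regularisation; a fixed-once dataset can be
  emulated by pre-distorting with `apply_policy()`.
* **3D rotations and shears** act in the axial plane, which is the
  appropriate small-angle family for the MRI preset.

## Training harness

The reference model is a small CNN: four 3^nd convolution blocks (ReLU,
2× average pooling), global average pooling (the penultimate features),
and a linear softmax or sigmoid head, trained with Adam at initial
learning rate 0.001, decayed multiplicatively by 5% every 2 epochs — the
most literal reading of "5% per 2 epochs". Early stopping counts an
epoch as improving only if the validation loss decreases by at least
1e-5 (guarding the patience counter against float jitter), and the
returned weights are those of the best validation epoch. Schedule presets
mirror the full-scale recipes (batch 128, patience 4/15 for the 2D task;
batch 16, patience 10/80 for 3D); unit tests and the shipped experiments
use the desk-scale default (batch 32, patience 4, 15 epochs), which
trains a 64×64 model in tens of seconds on one CPU. Any other classifier
can be plugged in by implementing `predict_scores()`,
`penultimate_features()`, `input_gradients()`, `freeze_backbone()` and
(optionally) `gradcam_ingredients()`.

Decision thresholds are selected per label on the validation set by
scanning the 101-point grid {0.00, 0.01, …, 1.00} for the maximum
support-weighted F1 over the positive and negative classes, ties broken
toward the smallest threshold; "predicted positive" means
`score >= threshold` everywhere in the package. Test-time augmentation
scores an image as the arithmetic mean of the adapter's scores over
`reps_per_method` copies per method (12 images at the default 3).

The task-transfer probe freezes the backbone, fits a fresh linear softmax
layer on the penultimate features with full-batch Adam (early-stopped on
validation cross-entropy), and reports the held-out macro one-vs-rest AUC
with a bootstrap interval. The probe sees unaugmented images; what is
being measured is what the *backbone* encoded during its own (augmented
or unaugmented) training.

## Metrics and fairness gaps

AUC is the Mann–Whitney statistic (ties count ½); BCE clips scores at
1e-7; ECE uses 10 equal-width right-closed bins (the convention of the
calibration literature; the bin count is exposed). Error rate and
precision at the global thresholds operationalise equalised odds and
equal opportunity. The **fairness gap** is `max - min` of a metric across
groups — the spread definition that reproduces two-group disparity tables
exactly — with a mean-pairwise-difference alternative behind a flag;
multi-label results are macro-averaged over labels with equal weight.
Bootstrap intervals resample individual test samples (not subjects) with
replacement, B = 1000 and seed 2021 by default; replicates on which a
statistic is undefined (e.g. a group losing one class) are dropped and
counted. Groups with undefined precision are excluded from that metric's
gap rather than imputed, to avoid manufacturing disparities.

## Association tests

The dependence audit crosses each label with the group attribute: a
Pearson chi-square test (no continuity correction; zero expected counts
are an error advising category merging) and a permutation test on the
in-sample AUC of a logistic regression from one-hot demographics to the
label. The logistic model is refitted on every permutation — the
comparison is against the AUC *of the refitted model* on shuffled labels
— which is affordable because the design has at most a handful of one-hot
columns. P-values use the add-one correction
`(1 + #{AUC_perm >= AUC_obs}) / (1 + B)`, which keeps them positive and
super-uniform under the null; defaults are B = 100,000 and alpha = 0.001.
Whether the original analysis used in-sample or held-out AUC is not
stated; in-sample is used here, matching a single-fit description.

## Debiasing comparators

All methods act on the label-detection task and share the training loop,
so augmentation can be layered onto any of them:

* **balanced** — subject-wise downsampling of every group to the minority
  group's subject count;
* **stratified** — one model per group, routed at inference;
* **adversarial** — a 2-layer perceptron predicts the group from the
  penultimate features; its cross-entropy enters the model's loss with
  weight `-lambda` via gradient reversal;
* **distmatch** — gamma times a penalty on per-group predicted-score
  batches: unbiased RBF-kernel MMD² (median-heuristic bandwidth, treated
  as constant under differentiation) or squared difference of group mean
  scores; multi-group attributes average over all unordered pairs;
* **fairalm** — augmented Lagrangian on the constraint c = difference of
  group-mean BCE risks (max pairwise difference beyond two groups):
  model steps on `task + mu c + (rho/2) c^2`, multiplier steps
  `mu <- mu + eta c` per epoch, aborting if `|mu| > 1e6`.

None of the source hyperparameters are published; the defaults
(lambda = 1, gamma = 1, eta = 0.01, rho = 1, hidden width 16) are exposed
in `debias_config()`. Every weighted method at weight 0 reproduces the
baseline trajectory bit-for-bit under a shared seed, which is enforced by
isolating each RNG stream (weight initialisation, adversary
initialisation, per-epoch shuffling/augmentation draws are all seeded
separately).

## Interpretation

Grad-CAM uses the last convolutional block (the layer is not specified in
the source; the last block is the standard choice), global-average-pooled
gradients as channel weights, rectification, upsampling and [0, 1]
rescaling. Integrated gradients use a zero baseline and a midpoint
Riemann rule (50 steps by default) — completeness (attributions summing
to the score difference from baseline) is verified in the tests at 200
steps within 5%. Mean saliency maps average |IG| over an image set and
summarise per-pixel magnitudes as a density histogram. "Accurately
identified" in the discordant-case selector means argmax agreement for
multi-class demographics and a 0.5 threshold for binary ones.

## Problem sizes, determinism and degenerate inputs

The shipped experiments run on one CPU: unit tests use 16–32 px images
and tens of subjects; the end-to-end audit uses 600 subjects at 64×64
with three seeds, which is the smallest configuration we found that
separates the augmented and unaugmented conditions cleanly while keeping
a full audit under a quarter of an hour. Every stochastic stage (cohort
generation, splitting, weight initialisation, epoch shuffling,
augmentation draws, bootstrap, permutations) takes an explicit seed, and
identical configurations reproduce results bit-for-bit. Degenerate inputs
are handled explicitly: constant labels are refused by the detector;
single-class groups lose AUC (with a warning) but keep the other metrics;
labels without validation positives fall back to threshold 0.5 with a
warning; precision with no predicted positives is flagged undefined and
excluded from gaps; empty MRI foregrounds fall back to full-volume
resizing with a warning.

## Known limitations

* The synthetic shortcut kinds are geometric by design; shortcut features
  that are distortion-invariant (global texture, intensity statistics)
  would survive this augmentation family, and `global_offset` exists
  precisely to model such a case (the audit detects it; the mitigation
  does not remove it).
* The reference CNN is a desk-scale stand-in; conclusions about absolute
  performance do not transfer to large pretrained architectures, only
  the audit mechanics do.
* The fisheye parameterisation is one reasonable barrel model among
  several.
* Statistical comparisons between debias methods (beyond bootstrap CIs)
  are out of scope, as are post-processing debias methods such as
  per-group threshold adjustment.
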