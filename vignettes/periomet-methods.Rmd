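---
title: "Methods: calibrated periocular landmark measurement"
author: "periomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated periocular landmark measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periomet)
```

## The measurement problem

Assessment of acquired (involutional) ptosis relies on a handful of
periocular distances: the margin reflex distances MRD1 and MRD2 (vertical
distance from the pupil center to the upper and lower eyelid margin) and
the height of the eyebrow above the pupil-center baseline. Manual
photographic measurement requires a human to choose a scale bar, a
baseline and landmark positions, which introduces inter- and intra-rater
variability. `periomet` automates the chain from a cropped single-eye
photograph to seven calibrated measurements:

1. two binary segmentation networks produce an iris mask and an eyebrow
   mask;
2. the *minimum enclosing circle* of the visible iris reconstructs the
   corneal outline even when the lids occlude part of it, and its center
   serves as the pupil-center (PC) proxy;
3. the circle diameter is equated with the mean adult horizontal corneal
   diameter of 11 mm, giving a per-image scale
   `mm_per_px = 11 / (2 * radius_px)`;
4. MRD1/MRD2 are read off the visible-iris extremal rows in a 3 px
   column band at the PC column, and eyebrow heights are measured at five
   columns — medial eyebrow end (MBE), medial limbus (ML), PC, lateral
   limbus (LL), lateral eyebrow end (LBE) — as the vertical distance from
   the PC row to the top of the eyebrow mask.

All images are normalized to left-periocular framing (right-side images
are mirrored), so the medial side is image-left throughout.

### Why the minimum enclosing circle

A ptotic upper lid truncates the iris, so neither a centroid nor an
ellipse fit of the visible mask estimates the corneal geometry reliably.
As long as the horizontal extremes of the iris (the limbus at the
equator) remain visible, the smallest circle containing the visible
pixels is exactly the corneal circle: any enclosing circle must contain
the two equatorial extremes, which are one corneal diameter apart. The
solver is a randomized incremental (Welzl-type, move-to-front) algorithm
with expected linear time, applied to the boundary pixels of the largest
8-connected component; an O(n^4) exhaustive solver over all point pairs
and triples ships alongside it as an independent oracle for testing.

Design choices worth stating explicitly:

* **Pupil-center proxy.** The center of the minimum enclosing circle is
  the only landmark that is stable under lid occlusion; a true corneal
  light reflex is not available from masks.
* **MRD from masks is clipped at zero.** A clinical MRD1 can be negative
  (lid margin below the pupil center), but a visible-iris measure cannot;
  the `occluded_top`/`occluded_bottom` flags record when the lid
  truncates the corneal outline so downstream analyses can treat those
  values as censored.
* **Coordinates.** 0-based, origin top-left, y grows downward; heights
  are `(PC_y - row) * mm_per_px` so "above" is positive. Components use
  8-connectivity; boundary pixels are foreground pixels with a
  4-neighbor background (the frame border counts as background); size
  ties between components break to the first foreground pixel in
  row-major order.

## Synthetic scenes with analytic ground truth

The clinical photographs this method targets are restricted, so the
package ships a generator that emulates their geometry with closed-form
ground truth. A scene is: an iris disk (radius 27–33 px on a 256 px
canvas, i.e. a scale of roughly 0.17–0.20 mm/px under the 11 mm
convention), two quadratic eyelid curves clipping it, a quadratic
eyebrow centerline thickened into a band and textured with hair strokes,
a skin-toned background, and Gaussian pixel noise. All randomness flows
from one integer seed through a counter-based splitting scheme, so every
scene is independently reproducible.

Ptosis severity parameterizes the upper-lid vertex between the iris top
(severity 0) and the pupil center (severity 1), which makes the analytic
ground truth exact: `MRD1 = 5.5 * (1 - severity)` mm. The default
severity distribution is uniform, centred so that the population mean
MRD1 equals 2.44 mm, and capped at half-width 0.40 (severity ≈
0.16–0.96, mild to severe-but-not-complete ptosis). The cap is a
numerical-fidelity choice: above severity ≈ 0.95 the visible iris
degenerates toward a half-disk, and the enclosing-circle center becomes
rasterization-limited (errors of 2–4 px were observed in a 300-scene
design sweep), which would break the generator's guarantee that
mask-based measurement reproduces analytic ground truth within 2 px.
Severity 1.0 remains available through an explicit
`scene_config(severity_range = c(1, 1))`. MRD2 is uniform
3.54 ± 1.0 mm. Eyebrow peak heights are 17–21 mm above the pupil center
with 5–7 mm band thickness — anatomically plausible values chosen once;
hair density spans 0.55–1.

Two stylizations depart deliberately from anatomy:

* the upper-lid margin curves *upward* away from the pupil axis, so the
  equatorial limbus stays visible at every severity and the corneal
  circle remains recoverable (a real lid margin droops toward the
  canthi; under severe ptosis that genuinely degrades circle recovery,
  which is a documented failure mode of the method, not of the
  implementation);
* the eyebrow ground-truth mask is the ideal band while the *rendered*
  hair strokes subsample it at `brow_density`, so sparse-brow
  segmentation difficulty is emulated without giving up analytic truth.

What passing tests on these scenes demonstrates is therefore the
correctness of the geometry chain and the trainability of the
segmentation models under controlled conditions — not clinical
performance on photographs, which involve specular highlights, makeup,
eyelashes, skin-fold shadows and annotation ambiguity that the generator
does not model.

## Segmentation models

Two independent single-channel networks (one for the iris, one for the
eyebrow) follow the U-Net pattern: a convolutional encoder at 64/32/16 px
with channel widths `w, 2w, 4w`, a bottleneck, and a decoder of
2×2-stride-2 transposed convolutions with skip concatenations, closed by
a 1×1 convolution producing a 64×64 logit map (sigmoid probabilities).
The engine is implemented natively in R: 3×3 convolutions run as
compiled im2col + BLAS GEMM kernels with exact adjoint backward passes,
verified against central-difference gradients to ~1e-9 relative error.
Training uses Adam on binary cross-entropy with logits, batch size 16,
initial learning rate 0.005 halved whenever the validation loss fails to
improve (strictly, by more than 1e-6) for 10 consecutive epochs, with
the best-validation-loss parameters retained. Images are resized to the
64×64 input bilinearly; masks by nearest-neighbor. The 0.5 probability
threshold is exposed as an argument. Training is fully deterministic for
a fixed seed: identical seeds give identical loss histories.

The default profile trains a width-8 model from seeded random
initialization. At that width the full desk-scale study — 200 training
scenes, 30 epochs, both tasks — runs in roughly five minutes on one CPU
and reaches held-out synthetic IoU ≈ 0.95 for both iris and eyebrow;
the problem sizes used by the test-suite fixtures (a width-6 model, 64
training scenes, 25 epochs) were chosen as the smallest that reliably
clear the paired untrained-model comparison and heatmap-localization
checks.

For inspection, `saliency_map()` returns the normalized absolute input
gradient of the summed foreground logit, and `grad_cam()` the rectified
channel-weighted activation map at a selectable decoder depth, both
upsampled to image size and normalized to [0, 1] after upsampling.
`measure_latency()` times single-image forward passes only, excluding
I/O, preprocessing and warm-up; its `threads` argument is advisory
metadata because BLAS threading cannot be reconfigured after load.

## Evaluation conventions

Pixel metrics follow the standard confusion-count formulas: accuracy,
precision, recall, F1 = 2·P·R/(P+R) and IoU = TP/(TP+FP+FN). Ratios with
zero denominators are reported as `NA` rather than 0 or 1 so degenerate
masks stay visible. Landmark accuracy uses RMSE (mm) and MAPE (%), with
the reference measurement as the MAPE denominator. In aggregated
reports, overall RMSE/MAPE are *unweighted means of the per-landmark
values*, not pooled over all image-landmark pairs — this is the only
aggregation under which the published per-landmark table reproduces its
printed overall values (2.48 mm, 4.00%, and 2.21% for the five-eyebrow
subgroup), and the package adopts it throughout. Occluded or missing
landmarks are excluded pairwise with exclusion counts reported.

## Splitting and degenerate inputs

`split_dataset()` allocates floor(n·ratio) items per subset and assigns
leftover items one at a time in the order train, test, val; 612 items at
0.8/0.1/0.1 give 490/61/61 and 10 give 8/1/1. The rule is deterministic
given the seed, warns when a subset ends up empty (e.g. 7 items →
6/0/1), and optionally groups by a patient column so bilateral samples
never straddle splits. Empty masks raise errors in the geometry chain
except where the contract says otherwise: a missing eyebrow at one
landmark column is a flagged `NA`, not an exception, because a partially
out-of-frame brow is an expected clinical condition.

## Known limitations

* Clipped-at-zero MRD and the occlusion flags understate severe ptosis;
  a negative MRD1 is not representable from masks.
* The 11 mm corneal constant is a population mean; individual deviation
  (11–12.5 mm) biases all millimetre outputs proportionally.
* The synthetic generator does not model specular highlights, eyelashes,
  makeup, glasses or full-face context, and its lid stylization removes
  the circle-recovery degradation that real severe ptosis causes.
* The pretrained-encoder transfer-learning path of the original training
  recipe is not available in a pure-R stack; models here train from
  seeded random initialization, which is sufficient for the synthetic
  benchmark but not a claim about clinical-scale performance.
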