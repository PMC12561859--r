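# periomet

Automated, calibrated measurement of periocular anatomy from cropped
single-eye photographs, aimed at objective ptosis assessment in
oculoplastics. The package covers the full chain used in AI-assisted
eyelid/eyebrow analysis:

* **Segmentation** — two compact U-Net-style binary networks (iris,
  eyebrow) trained natively in R (compiled im2col/GEMM convolution
  kernels, Adam, BCE-with-logits, reduce-on-plateau scheduling), with
  saliency-map and Grad-CAM inspection and CPU latency benchmarking.
* **Geometry** — recovery of the corneal outline from a lid-occluded
  iris mask via the minimum enclosing circle (randomized incremental
  solver, plus an exhaustive O(n^4) oracle for verification),
  calibration with the 11 mm horizontal corneal diameter, and derivation
  of seven landmarks: MRD1, MRD2, and eyebrow heights at the medial
  eyebrow end (MBE), medial limbus (ML), pupil center (PC), lateral
  limbus (LL) and lateral eyebrow end (LBE).
* **Synthetic scenes** — a generator emulating ptosis-clinic periocular
  crops (iris disk occluded by eyelid curves, textured eyebrow arc,
  noisy skin background) with pixel-exact masks and closed-form landmark
  ground truth, so the whole pipeline is testable end-to-end without
  restricted clinical data.
* **Evaluation** — confusion-count segmentation metrics (accuracy,
  precision, recall, F1, IoU) and per-landmark RMSE/MAPE error reports
  with the unweighted-mean aggregation convention.

The core calibration identity is `mm_per_px = 11 / (2 * r)`, where `r`
is the radius (px) of the minimum enclosing circle of the visible iris;
MRD1/MRD2 are the distances from the circle center to the visible-iris
extremal rows at the pupil-center column, and brow heights are vertical
distances from the circle center row to the top of the eyebrow mask at
the five landmark columns.

## Worked example

```r
library(periomet)

params <- sample_scene_params(scene_config(), seed = 42)
scene  <- render_scene(params)
lm     <- measure_all(scene$truth$iris_mask, scene$truth$brow_mask)
lm
#> MRD1 0.96 mm, MRD2 3.96 mm (scale 0.1695 mm/px)
#> brow heights (mm):
#>   MBE    ML    PC    LL   LBE
#> 16.04 20.79 21.81 21.98 20.96

scene$truth$landmarks          # analytic ground truth of the same scene
#> MRD1 0.99 mm, MRD2 4.01 mm (scale 0.1693 mm/px)
#> brow heights (mm):
#>   MBE    ML    PC    LL   LBE
#> 15.87 20.82 21.82 22.04 20.88
```

The mask-based measurement reproduces the scene's analytic ground truth
to a fraction of a millimetre (the generator guarantees agreement within
2 px times the calibrated scale, here about 0.34 mm). A severity-0.9
scene like this one has most of its iris hidden under the upper lid —
the small MRD1 with an intact 11 mm calibration is exactly the situation
the minimum-enclosing-circle construction is for.

Training a segmentation model on generated scenes:

```r
scenes <- generate_scenes(240, scene_config(), seed = 1)
train  <- scenes_to_tensors(scenes[1:200], task = "iris")
val    <- scenes_to_tensors(scenes[201:240], task = "iris")
fit    <- train_model(build_model(width = 8, seed = 1), train, val,
                      train_config(max_epochs = 30, seed = 1))
pred   <- predict_mask(fit$model, scenes[[201]]$image)
```

A command-line interface wrapping these functions (commands `generate`,
`train`, `segment`, `measure`, `evaluate`, `explain`, `benchmark`) is
installed at `inst/cli/periomet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/periomet.R", package="periomet"))')" \
    measure --iris iris.png --brow brow.png --medial left
```

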