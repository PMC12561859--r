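# Synthetic scene generator: determinism, population anchors, analytic
# ground truth, and rendering invariants.

test_that("scene sampling is deterministic for a fixed (config, seed)", {
  cfg <- scene_config()
  expect_identical(sample_scene_params(cfg, seed = 1),
                   sample_scene_params(cfg, seed = 1))
  expect_false(identical(sample_scene_params(cfg, seed = 1),
                         sample_scene_params(cfg, seed = 2)))
})

test_that("degenerate configuration ranges are rejected", {
  expect_error(scene_config(iris_radius_px = c(33, 27)), "degenerate")
  expect_error(scene_config(brow_density = c(0, 1)), "density")
  expect_error(scene_config(mrd1_mean_mm = 6), "mm")
})

test_that("population means of MRD1/MRD2 match the configured targets", {
  cfg <- scene_config()  # targets 2.44 mm and 3.54 mm
  lms <- vapply(1:2000, function(i) {
    lm <- ground_truth_landmarks(sample_scene_params(cfg, seed = i))
    c(lm$mrd1_mm, lm$mrd2_mm)
  }, numeric(2))
  expect_lt(abs(mean(lms[1, ]) - 2.44), 0.1)
  expect_lt(abs(mean(lms[2, ]) - 3.54), 0.1)
})

test_that("complete ptosis forces analytic MRD1 to zero", {
  cfg <- scene_config(severity_range = c(1, 1))
  for (seed in 1:20) {
    lm <- ground_truth_landmarks(sample_scene_params(cfg, seed = seed))
    expect_equal(lm$mrd1_mm, 0)
  }
})

test_that("analytic MRD1 is non-increasing in ptosis severity", {
  base <- sample_scene_params(scene_config(), seed = 5)
  cx <- base$iris_center[1]; cy <- base$iris_center[2]; r <- base$iris_radius
  a_u <- base$upper_lid_curve[3]
  mrd1_at <- function(s) {
    p <- base
    vert <- cy - r * (1 - s)
    p$upper_lid_curve <- c(a_u * cx^2 + vert, -2 * a_u * cx, a_u)
    p$ptosis_severity <- s
    ground_truth_landmarks(p)$mrd1_mm
  }
  sweep <- vapply(seq(0, 1, by = 0.05), mrd1_at, numeric(1))
  expect_true(all(diff(sweep) <= 1e-12))
  expect_equal(sweep[length(sweep)], 0)
})

test_that("rendering is deterministic and masks are binary and disjoint", {
  p <- sample_scene_params(scene_config(), seed = 42)
  s1 <- render_scene(p); s2 <- render_scene(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth$iris_mask, s2$truth$iris_mask)
  expect_identical(s1$truth$brow_mask, s2$truth$brow_mask)
  expect_type(s1$truth$iris_mask, "logical")
  expect_false(any(s1$truth$iris_mask & s1$truth$brow_mask))
  expect_equal(dim(s1$image), c(p$image_height, p$image_width, 3))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
})

test_that("an unoccluded iris renders as the full disk", {
  # severity 0 (lid at iris top) and lower lid pushed below the disk
  p <- scene_params(
    image_height = 128, image_width = 128,
    iris_center = c(64, 70), iris_radius = 20,
    upper_lid_curve = c(70 - 20 - 1), lower_lid_curve = c(70 + 20 + 2),
    ptosis_severity = 0,
    brow_arc = c(20), brow_thickness = 10, brow_density = 1,
    brow_span = c(20, 108), noise_sd = 0.01, seed = 3
  )
  sc <- render_scene(p)
  expect_lt(abs(sum(sc$truth$iris_mask) - pi * 20^2) / (pi * 20^2), 0.01)
})

test_that("full-density brow mask equals an independently rasterized band", {
  p <- sample_scene_params(scene_config(brow_density = c(1, 1)), seed = 9)
  sc <- render_scene(p)
  # oracle: direct per-pixel rasterization of the ideal band
  h <- p$image_height; w <- p$image_width
  oracle <- matrix(FALSE, h, w)
  for (col in seq_len(w)) {
    x <- col - 1
    if (x < p$brow_span[1] || x > p$brow_span[2]) next
    yc <- poly_eval(p$brow_arc, x)
    rows <- which(abs((seq_len(h) - 1) - yc) <= p$brow_thickness / 2)
    oracle[rows, col] <- TRUE
  }
  expect_identical(sc$truth$brow_mask, oracle)
  expect_equal(sum(sc$truth$brow_mask), sum(oracle))
})

test_that("analytic landmarks evaluate the stated polynomials exactly", {
  mk <- function(brow_arc) scene_params(
    image_height = 200, image_width = 200,
    iris_center = c(100, 150), iris_radius = 25,
    upper_lid_curve = c(150 - 25), lower_lid_curve = c(150 + 15),
    ptosis_severity = 0,
    brow_arc = brow_arc, brow_thickness = 12, brow_density = 0.8,
    brow_span = c(30, 180), seed = 1
  )
  mmpp <- 11 / 50

  # flat arc at constant height: all five brow heights equal
  flat <- ground_truth_landmarks(mk(c(60)))
  expect_true(all(abs(flat$brow_mm - (150 - (60 - 6)) * mmpp) < 1e-9))

  # cubic arc: heights equal direct polynomial evaluation at the columns
  coefs <- c(90, -0.45, 3e-3, -8e-6)
  lm <- ground_truth_landmarks(mk(coefs))
  for (nm in names(lm$columns_px)) {
    x <- lm$columns_px[[nm]]
    expected <- (150 - (poly_eval(coefs, x) - 6)) * mmpp
    expect_equal(lm$brow_mm[[nm]], expected, tolerance = 1e-9)
  }

  # a required limbus column outside the brow span: flagged missing value
  # (ML sits at column 75 = 100 - 25; span starting at 90 cannot cover it)
  short <- mk(c(60)); short$brow_span <- c(90, 180)
  lm2 <- ground_truth_landmarks(short)
  expect_true(is.na(lm2$brow_mm[["ML"]]))
  expect_true(lm2$occlusion[["ML"]])
  expect_false(lm2$occlusion[["MBE"]])
})

test_that("invalid scene geometry is rejected", {
  expect_error(scene_params(
    image_height = 100, image_width = 100,
    iris_center = c(90, 50), iris_radius = 20,
    upper_lid_curve = c(30), lower_lid_curve = c(70), ptosis_severity = 0,
    brow_arc = c(10), brow_thickness = 5, brow_density = 1,
    brow_span = c(10, 90)
  ), "frame")
  expect_error(scene_params(
    image_height = 256, image_width = 256,
    iris_center = c(128, 160), iris_radius = 30,
    upper_lid_curve = c(200), lower_lid_curve = c(150), ptosis_severity = 0.5,
    brow_arc = c(40), brow_thickness = 10, brow_density = 1,
    brow_span = c(30, 220)
  ), "lid")
})

test_that("persisted datasets are reproducible and internally consistent", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man1 <- generate_dataset(10, scene_config(), seed = 7, dir = dir1)
  man2 <- generate_dataset(10, scene_config(), seed = 7, dir = dir2)
  expect_equal(nrow(man1), 10)
  expect_identical(man1[setdiff(names(man1), c())], man2)
  # identical files byte-for-byte
  for (f in c(man1$image_path[1], man1$iris_mask_path[1])) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  }
  loaded <- load_manifest(file.path(dir1, "manifest.csv"))
  expect_equal(nrow(loaded), 10)
  # landmarks in the manifest match re-measurement from the stored masks
  i <- which(loaded$side == "left")[1]
  iris <- read_mask(file.path(dir1, loaded$iris_mask_path[i]))
  brow <- read_mask(file.path(dir1, loaded$brow_mask_path[i]))
  m <- measure_all(iris, brow)
  expect_equal(m$mrd2_mm, loaded$MRD2[i], tolerance = 2 * loaded$mm_per_px[i])
  expect_equal(m$brow_mm[["PC"]], loaded$PC[i],
               tolerance = 2 * loaded$mm_per_px[i])
})
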