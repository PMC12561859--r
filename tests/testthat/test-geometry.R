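# Landmark geometry: component filtering, boundary extraction, minimum
# enclosing circle, calibration, and the measurement chain.

test_that("largest_component keeps the dominant blob and drops speckle", {
  m <- matrix(FALSE, 20, 20)
  m[3:12, 3:7] <- TRUE            # 50 px blob
  m[16:17, 16] <- TRUE            # 2 px speckle
  m[1, 20] <- TRUE                # 1 px speckle
  out <- largest_component(m)
  expect_equal(sum(out), 50)
  expect_true(all(which(out) %in% which(m)))

  single <- matrix(FALSE, 5, 5); single[2:3, 2:4] <- TRUE
  expect_identical(largest_component(single), single)

  expect_error(largest_component(matrix(FALSE, 4, 4)), "empty")
})

test_that("largest_component uses 8-connectivity", {
  m <- matrix(FALSE, 6, 6)
  # diagonal staircase: one component under 8-connectivity
  for (i in 1:5) m[i, i] <- TRUE
  expect_equal(sum(largest_component(m)), 5)
})

test_that("equal-size components tie-break on the first row-major pixel", {
  # exhaustive check over all placements of two disjoint 2x2 blobs in 10x10
  put <- function(r, c) {
    m <- matrix(FALSE, 10, 10); m[r:(r + 1), c:(c + 1)] <- TRUE; m
  }
  cases <- list(c(2, 2, 7, 7), c(7, 7, 2, 2), c(2, 7, 2, 2), c(5, 5, 5, 8))
  for (cs in cases) {
    m <- put(cs[1], cs[2]) | put(cs[3], cs[4])
    out <- largest_component(m)
    # winner contains the first foreground pixel in row-major order
    scan <- which(t(m))[1]
    expect_true(t(out)[scan], info = paste(cs, collapse = ","))
    expect_equal(sum(out), 4)
  }
})

test_that("boundary_points excludes interior pixels and preserves the circle", {
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  bp <- boundary_points(sq)
  expect_equal(nrow(bp), 8)       # 3x3 square: all but the center pixel

  single <- matrix(FALSE, 3, 3); single[2, 3] <- TRUE
  expect_equal(unname(boundary_points(single)), cbind(2, 1))

  set.seed(71)
  for (i in 1:50) {
    blob <- random_blob()
    full <- which(blob, arr.ind = TRUE)
    full_pts <- cbind(full[, "col"] - 1, full[, "row"] - 1)
    c_full <- min_enclosing_circle(full_pts)
    c_bd <- min_enclosing_circle(boundary_points(blob))
    expect_true(circles_equal(c_full, c_bd, tol = 1e-9))
  }
})

test_that("minimum enclosing circle solves the closed-form cases", {
  c1 <- min_enclosing_circle(rbind(c(3, 4)))
  expect_equal(c1$center, c(3, 4))
  expect_equal(c1$radius, 0)

  c2 <- min_enclosing_circle(rbind(c(0, 0), c(2, 0)))
  expect_equal(c2$center, c(1, 0))
  expect_equal(c2$radius, 1)

  # acute triangle: minimum circle is the circumcircle
  c3 <- min_enclosing_circle(rbind(c(0, 0), c(4, 0), c(2, 3)))
  expect_equal(c3$center, c(2, 5 / 6), tolerance = 1e-9)
  expect_equal(c3$radius, 13 / 6, tolerance = 1e-9)

  expect_error(min_enclosing_circle(matrix(numeric(0), 0, 2)), "point")
})

test_that("Welzl solver matches the brute-force oracle on random sets", {
  set.seed(4213)
  for (i in 1:60) {
    n <- sample(1:25, 1)
    pts <- matrix(runif(2 * n, 0, 100), ncol = 2)
    a <- min_enclosing_circle(pts)
    b <- min_enclosing_circle_bruteforce(pts)
    expect_true(circles_equal(a, b, tol = 1e-7), info = paste("set", i))
  }
})

test_that("the enclosing circle is invariant to input order", {
  set.seed(99)
  pts <- matrix(runif(60, 0, 50), ncol = 2)
  ref <- min_enclosing_circle(pts)
  for (i in 1:10) {
    shuf <- pts[sample(nrow(pts)), ]
    expect_true(circles_equal(ref, min_enclosing_circle(shuf), tol = 1e-9))
  }
})

test_that("brute-force solver handles degenerate layouts", {
  expect_equal(min_enclosing_circle_bruteforce(rbind(c(1, 2)))$radius, 0)
  # collinear points: diameter circle of the extreme pair
  col <- cbind(seq(0, 8, by = 2), rep(3, 5))
  b <- min_enclosing_circle_bruteforce(col)
  expect_equal(b$center, c(4, 3), tolerance = 1e-9)
  expect_equal(b$radius, 4, tolerance = 1e-9)
})

test_that("calibration follows the 11 mm corneal convention", {
  expect_equal(calibrate_scale(list(center = c(0, 0), radius = 5.5))$mm_per_px, 1.0)
  s <- calibrate_scale(list(center = c(0, 0), radius = 10))
  expect_equal(s$mm_per_px, 0.55)
  expect_equal(s$reference_diameter_mm, 11)
  expect_error(calibrate_scale(list(center = c(0, 0), radius = 0)), "positive")
})

test_that("landmark columns derive from circle and brow extremes", {
  brow <- matrix(FALSE, 60, 60); brow[5:10, 6:51] <- TRUE  # cols 5..50 0-based
  circ <- list(center = c(32, 40), radius = 10)
  cols <- landmark_columns(circ, brow, medial = "left")
  expect_equal(unname(cols), c(5, 22, 32, 42, 50))
  colsR <- landmark_columns(circ, brow, medial = "right")
  expect_equal(unname(colsR[c("ML", "LL")]), c(42, 22))
  expect_equal(unname(colsR[c("MBE", "LBE")]), c(50, 5))
  expect_error(landmark_columns(circ, brow & FALSE), "empty")
})

test_that("brow heights measure the band top above the pupil center", {
  brow <- matrix(FALSE, 60, 60); brow[11:16, 21:41] <- TRUE  # top row y=10
  scale <- list(mm_per_px = 0.55)
  h <- brow_height_at(brow, 30, pupil_center = c(30, 30), scale)
  expect_equal(h$height_mm, 20 * 0.55)  # 11 mm
  expect_false(h$missing)

  # top of brow at the pupil-center row: zero height
  at_zero <- brow_height_at(brow, 30, pupil_center = c(30, 10), scale)
  expect_equal(at_zero$height_mm, 0)

  # no brow pixels within the band: flagged missing, not an error
  miss <- brow_height_at(brow, 55, pupil_center = c(30, 30), scale)
  expect_true(miss$missing)
  expect_true(is.na(miss$height_mm))
})

test_that("MRD measurement handles clipped and unclipped disks", {
  full <- disk_mask(41, 41, 20, 20, 10)
  circ <- min_enclosing_circle(boundary_points(full))
  scale <- calibrate_scale(circ)
  m <- measure_mrd(full, circ, scale)
  expect_equal(m$mrd1_mm, 5.5, tolerance = 0.02)
  expect_equal(m$mrd2_mm, 5.5, tolerance = 0.02)
  expect_false(m$occluded_top)
  expect_false(m$occluded_bottom)

  # upper lid clipping 4 px above center
  yg <- matrix(0:40, 41, 41)
  clipped <- full & yg >= 16
  m2 <- measure_mrd(clipped, circ, scale)
  expect_equal(m2$mrd1_mm, 4 * scale$mm_per_px, tolerance = 1e-9)
  expect_true(m2$occluded_top)

  # lid at the center row: MRD1 exactly zero
  half <- full & yg >= 20
  m3 <- measure_mrd(half, circ, scale)
  expect_equal(m3$mrd1_mm, 0)
})

test_that("measure_all recovers analytic landmarks on generated scenes", {
  for (seed in c(101, 202, 303, 404, 505)) {
    sc <- cached_scene(seed)
    m <- measure_all(sc$truth$iris_mask, sc$truth$brow_mask)
    gt <- sc$truth$landmarks
    tol <- 2 * gt$mm_per_px
    expect_lt(abs(m$mrd1_mm - gt$mrd1_mm), tol)
    expect_lt(abs(m$mrd2_mm - gt$mrd2_mm), tol)
    expect_true(all(abs(m$brow_mm - gt$brow_mm) < tol))
  }
})

test_that("measurements are mirror- and translation-invariant", {
  sc <- cached_scene(101)
  iris <- sc$truth$iris_mask; brow <- sc$truth$brow_mask
  ref <- measure_all(iris, brow, medial = "left")

  mir_iris <- iris[, rev(seq_len(ncol(iris)))]
  mir_brow <- brow[, rev(seq_len(ncol(brow)))]
  mir <- measure_all(mir_iris, mir_brow, medial = "right")
  expect_equal(mir$mrd1_mm, ref$mrd1_mm, tolerance = 1e-9)
  expect_equal(mir$mrd2_mm, ref$mrd2_mm, tolerance = 1e-9)
  expect_equal(mir$brow_mm, ref$brow_mm, tolerance = 1e-9)

  shift <- function(m, dy, dx) {
    out <- matrix(FALSE, nrow(m) + dy, ncol(m) + dx)
    out[dy + seq_len(nrow(m)), dx + seq_len(ncol(m))] <- m
    out
  }
  tr <- measure_all(shift(iris, 7, 11), shift(brow, 7, 11))
  expect_equal(tr$mrd1_mm, ref$mrd1_mm, tolerance = 1e-9)
  expect_equal(tr$brow_mm, ref$brow_mm, tolerance = 1e-9)
  expect_equal(tr$pupil_center, ref$pupil_center + c(11, 7), tolerance = 1e-9)
})

test_that("integer upscaling leaves millimetre values nearly unchanged", {
  sc <- cached_scene(202)
  up <- function(m, k) m[rep(seq_len(nrow(m)), each = k),
                         rep(seq_len(ncol(m)), each = k)]
  ref <- measure_all(sc$truth$iris_mask, sc$truth$brow_mask)
  big <- measure_all(up(sc$truth$iris_mask, 2), up(sc$truth$brow_mask, 2))
  # pixel replication thickens the boundary by half a pixel, so the
  # calibrated scale shifts by ~0.5/(2r) relative
  expect_equal(big$mm_per_px, ref$mm_per_px / 2, tolerance = 0.02)
  expect_equal(big$mrd1_mm, ref$mrd1_mm, tolerance = 2 * big$mm_per_px)
  expect_equal(big$brow_mm, ref$brow_mm, tolerance = 2 * big$mm_per_px)
})
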