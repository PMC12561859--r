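## Synthetic periocular scene generator.
##
## Emulates cropped single-eye photographs of ptosis patients: an iris
## disk partially occluded by upper/lower eyelid curves, a textured
## eyebrow arc above it, and a noisy skin-toned background. Every scene
## carries pixel-exact iris/eyebrow masks and closed-form landmark ground
## truth, so the full measurement chain can be validated without any
## clinical data.
##
## Geometry is parameterized so that MRD1 follows ptosis severity
## exactly: the upper-lid vertex sits at iris top for severity 0 and at
## the pupil center for severity 1, giving MRD1 = 5.5 * (1 - severity) mm
## under the 11 mm corneal calibration. Lid curvature signs are chosen so
## the medial/lateral limbus always stays visible, which keeps the
## corneal outline recoverable by the minimum enclosing circle at every
## severity.

#' Generator configuration for synthetic periocular scenes
#'
#' Defaults emulate the clinical measurement setting: 256 x 256 px crops,
#' iris radius 27-33 px (so one image spans roughly 43-47 mm), ptosis
#' severities spanning mild to complete (severity range derived from the
#' target population mean MRD1 of 2.44 mm; since MRD1 = 5.5*(1-severity)
#' mm, the default uniform severity range is centred on
#' 1 - 2.44/5.5 and widened until it touches severity 1), MRD2 centred on
#' 3.54 mm, eyebrow arcs 17-21 mm above the pupil center with hair
#' density 0.55-1.
#'
#' @param image_size canvas side length, px.
#' @param mrd1_mean_mm,mrd2_mean_mm target population means of the
#'   ground-truth margin reflex distances, mm.
#' @param severity_range optional explicit uniform range for ptosis
#'   severity in `[0, 1]`; overrides the range derived from
#'   `mrd1_mean_mm`.
#' @param severity_halfwidth cap on the half-width of the derived
#'   severity range (default 0.40, giving roughly severity 0.16-0.96:
#'   mild to severe-but-not-complete ptosis).
#' @param mrd2_halfwidth_mm half-width of the uniform MRD2 distribution.
#' @param iris_radius_px,iris_center_x_px,iris_center_y_px uniform ranges.
#' @param upper_lid_curv,lower_lid_curv quadratic lid coefficients
#'   (px^-1); upper is negative (margin rises away from the pupil axis),
#'   lower positive.
#' @param brow_peak_height_mm,brow_thickness_mm,brow_density,
#'   brow_span_min_px,brow_span_max_px,brow_peak_x_px,brow_curv
#'   eyebrow geometry ranges.
#' @param skin_tone base skin RGB in `[0, 1]`.
#' @param noise_sd_range pixel noise standard deviation range.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = 256L,
                         mrd1_mean_mm = 2.44,
                         mrd2_mean_mm = 3.54,
                         severity_range = NULL,
                         severity_halfwidth = 0.40,
                         mrd2_halfwidth_mm = 1.0,
                         iris_radius_px = c(27, 33),
                         iris_center_x_px = c(118, 138),
                         iris_center_y_px = c(154, 170),
                         upper_lid_curv = c(-0.010, -0.004),
                         lower_lid_curv = c(0.002, 0.010),
                         brow_peak_height_mm = c(17, 21),
                         brow_thickness_mm = c(5, 7),
                         brow_density = c(0.55, 1.0),
                         brow_span_min_px = c(28, 52),
                         brow_span_max_px = c(204, 228),
                         brow_peak_x_px = c(145, 170),
                         brow_curv = c(8e-4, 2.2e-3),
                         skin_tone = c(0.87, 0.67, 0.55),
                         noise_sd_range = c(0.01, 0.03)) {
  half_diam <- 5.5  # mm, corneal radius under the 11 mm convention
  if (is.null(severity_range)) {
    s_mid <- 1 - mrd1_mean_mm / half_diam
    if (s_mid <= 0 || s_mid >= 1) {
      stop_input("mrd1_mean_mm must lie strictly inside (0, 5.5) mm")
    }
    # mean-preserving uniform range; the cap keeps the default population
    # short of complete ptosis, where the visible iris degenerates to a
    # half-disk and sub-pixel circle recovery becomes rasterization-limited
    hw <- min(s_mid, 1 - s_mid, severity_halfwidth)
    severity_range <- c(s_mid - hw, s_mid + hw)
  }
  cfg <- list(
    image_size = as.integer(image_size),
    mrd1_mean_mm = mrd1_mean_mm,
    mrd2_mean_mm = mrd2_mean_mm,
    severity_range = severity_range,
    mrd2_range_mm = c(mrd2_mean_mm - mrd2_halfwidth_mm,
                      mrd2_mean_mm + mrd2_halfwidth_mm),
    iris_radius_px = iris_radius_px,
    iris_center_x_px = iris_center_x_px,
    iris_center_y_px = iris_center_y_px,
    upper_lid_curv = upper_lid_curv,
    lower_lid_curv = lower_lid_curv,
    brow_peak_height_mm = brow_peak_height_mm,
    brow_thickness_mm = brow_thickness_mm,
    brow_density = brow_density,
    brow_span_min_px = brow_span_min_px,
    brow_span_max_px = brow_span_max_px,
    brow_peak_x_px = brow_peak_x_px,
    brow_curv = brow_curv,
    skin_tone = skin_tone,
    noise_sd_range = noise_sd_range
  )
  ranges <- cfg[vapply(cfg, function(x) is.numeric(x) && length(x) == 2L,
                       logical(1))]
  bad <- names(ranges)[vapply(ranges, function(r) r[1] > r[2], logical(1))]
  if (length(bad)) {
    stop_input("degenerate configuration range(s): ",
               paste(bad, collapse = ", "))
  }
  if (severity_range[1] < 0 || severity_range[2] > 1) {
    stop_input("severity_range must lie within [0, 1]")
  }
  if (cfg$brow_density[1] <= 0 || cfg$brow_density[2] > 1) {
    stop_input("brow_density range must lie within (0, 1]")
  }
  structure(cfg, class = "scene_config")
}

#' Construct and validate scene parameters
#'
#' Low-level constructor for a single synthetic scene. Checks the
#' geometric invariants: the iris disk lies fully inside the frame, the
#' upper lid never sits below the lower lid over the iris span, the
#' eyebrow band and iris disk are disjoint, and severity lies in `[0, 1]`.
#'
#' @param image_height,image_width canvas size, px.
#' @param iris_center numeric `(x, y)`, 0-based, sub-pixel.
#' @param iris_radius px.
#' @param upper_lid_curve,lower_lid_curve polynomial coefficients
#'   (intercept first) giving lid margin y per column.
#' @param ptosis_severity in `[0, 1]`; 0 = lid at iris top, 1 = lid at
#'   pupil center.
#' @param brow_arc polynomial coefficients giving brow centerline y per
#'   column.
#' @param brow_thickness band thickness, px.
#' @param brow_density fraction of eyebrow columns rendered as hair
#'   strokes, in `(0, 1]`.
#' @param brow_span numeric `(x_min, x_max)`, px.
#' @param skin_tone RGB triple in `[0, 1]`.
#' @param noise_sd pixel noise standard deviation.
#' @param seed integer seed for the scene's own randomness (strokes,
#'   noise).
#' @return a `scene_params` list.
#' @export
scene_params <- function(image_height, image_width, iris_center, iris_radius,
                         upper_lid_curve, lower_lid_curve, ptosis_severity,
                         brow_arc, brow_thickness, brow_density, brow_span,
                         skin_tone = c(0.87, 0.67, 0.55), noise_sd = 0.02,
                         seed = 0L) {
  p <- structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    iris_center = as.numeric(iris_center),
    iris_radius = as.numeric(iris_radius),
    upper_lid_curve = as.numeric(upper_lid_curve),
    lower_lid_curve = as.numeric(lower_lid_curve),
    ptosis_severity = as.numeric(ptosis_severity),
    brow_arc = as.numeric(brow_arc),
    brow_thickness = as.numeric(brow_thickness),
    brow_density = as.numeric(brow_density),
    brow_span = as.numeric(brow_span),
    skin_tone = as.numeric(skin_tone),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "scene_params")
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  cx <- p$iris_center[1]; cy <- p$iris_center[2]; r <- p$iris_radius
  if (r <= 0) stop_input("iris_radius must be positive")
  if (cx - r < 0 || cx + r > p$image_width - 1 ||
      cy - r < 0 || cy + r > p$image_height - 1) {
    stop_input("iris disk extends outside the image frame")
  }
  if (p$ptosis_severity < 0 || p$ptosis_severity > 1) {
    stop_input("ptosis_severity must lie in [0, 1]")
  }
  if (p$brow_density <= 0 || p$brow_density > 1) {
    stop_input("brow_density must lie in (0, 1]")
  }
  if (p$brow_span[1] >= p$brow_span[2]) stop_input("degenerate brow_span")
  xs <- seq(floor(cx - r), ceiling(cx + r))
  if (any(poly_eval(p$upper_lid_curve, xs) >
          poly_eval(p$lower_lid_curve, xs) + 1e-9)) {
    stop_input("upper lid sits below lower lid over the iris span")
  }
  # brow band must stay clear of the iris disk
  bx <- seq(ceiling(p$brow_span[1]), floor(p$brow_span[2]))
  bx_iris <- bx[abs(bx - cx) <= r]
  if (length(bx_iris)) {
    band_bottom <- poly_eval(p$brow_arc, bx_iris) + p$brow_thickness / 2
    disk_top <- cy - sqrt(pmax(0, r^2 - (bx_iris - cx)^2))
    if (any(band_bottom >= disk_top - 1)) {
      stop_input("eyebrow band overlaps the iris region")
    }
  }
  invisible(p)
}

#' Sample scene parameters from a generator configuration
#'
#' Deterministic for a fixed `(config, seed)` pair. Under the default
#' configuration the population means of the analytic ground-truth MRD1
#' and MRD2 equal the configured targets (2.44 mm and 3.54 mm).
#'
#' @param config a [scene_config()].
#' @param seed non-negative integer.
#' @return a validated `scene_params`.
#' @export
sample_scene_params <- function(config = scene_config(), seed = 0L) {
  stopifnot(inherits(config, "scene_config"), seed >= 0)
  withr::with_seed(as.integer(seed %% 2147483647), {
    u <- function(r) runif(1, r[1], r[2])
    size <- config$image_size
    r <- u(config$iris_radius_px)
    cx <- u(config$iris_center_x_px)
    cy <- u(config$iris_center_y_px)
    mmpp <- 11 / (2 * r)
    s <- u(config$severity_range)
    a_u <- u(config$upper_lid_curv)
    a_l <- u(config$lower_lid_curv)
    d2_px <- u(config$mrd2_range_mm) / mmpp
    # quadratics in vertex form, expanded to coefficient vectors
    vert_u <- cy - r * (1 - s)
    vert_l <- cy + d2_px
    upper <- c(a_u * cx^2 + vert_u, -2 * a_u * cx, a_u)
    lower <- c(a_l * cx^2 + vert_l, -2 * a_l * cx, a_l)
    span <- c(u(config$brow_span_min_px), u(config$brow_span_max_px))
    xpk <- u(config$brow_peak_x_px)
    peak_y <- cy - u(config$brow_peak_height_mm) / mmpp
    th_px <- u(config$brow_thickness_mm) / mmpp
    max_off <- max(abs(span - xpk))
    curv_cap <- (cy - r - 10 - peak_y - th_px / 2) / max_off^2
    b2 <- u(c(config$brow_curv[1], min(config$brow_curv[2], curv_cap)))
    arc <- c(b2 * xpk^2 + peak_y, -2 * b2 * xpk, b2)
    tone <- clip01(config$skin_tone + runif(3, -0.04, 0.04))
    scene_params(
      image_height = size, image_width = size,
      iris_center = c(cx, cy), iris_radius = r,
      upper_lid_curve = upper, lower_lid_curve = lower,
      ptosis_severity = s,
      brow_arc = arc, brow_thickness = th_px,
      brow_density = u(config$brow_density), brow_span = span,
      skin_tone = tone, noise_sd = u(config$noise_sd_range),
      seed = seed_child(seed, 7L)
    )
  })
}

#' Analytic ground-truth landmarks of a scene
#'
#' Closed-form evaluation of the lid and brow polynomials; no
#' rasterization is involved. MRD1/MRD2 follow the visible-iris extent at
#' the exact pupil-center abscissa; brow heights are evaluated at the five
#' landmark columns (MBE, ML, PC, LL, LBE). A landmark column outside the
#' brow span yields `NA` with its missing flag set.
#'
#' @param params a `scene_params`.
#' @return a `landmark_set` (see [measure_all()]).
#' @export
ground_truth_landmarks <- function(params) {
  validate_scene_params(params)
  cx <- params$iris_center[1]; cy <- params$iris_center[2]
  r <- params$iris_radius
  mmpp <- 11 / (2 * r)
  lid_u <- poly_eval(params$upper_lid_curve, cx)
  lid_l <- poly_eval(params$lower_lid_curve, cx)
  top <- max(lid_u, cy - r)
  bottom <- min(lid_l, cy + r)
  cols <- c(MBE = round(params$brow_span[1]), ML = round(cx - r),
            PC = round(cx), LL = round(cx + r), LBE = round(params$brow_span[2]))
  in_span <- cols >= params$brow_span[1] - 0.5 & cols <= params$brow_span[2] + 0.5
  brow_top <- poly_eval(params$brow_arc, cols) - params$brow_thickness / 2
  brow_mm <- ifelse(in_span, (cy - brow_top) * mmpp, NA_real_)
  names(brow_mm) <- names(cols)
  occl <- c(MRD1 = top > (cy - r) + 1, MRD2 = bottom < (cy + r) - 1,
            !in_span)
  names(occl) <- c("MRD1", "MRD2", names(cols))
  structure(list(
    mrd1_mm = max(0, (cy - top) * mmpp),
    mrd2_mm = max(0, (bottom - cy) * mmpp),
    brow_mm = brow_mm,
    columns_px = as.integer(cols) |> setNames(names(cols)),
    pupil_center = c(cx, cy),
    radius_px = r,
    mm_per_px = mmpp,
    occlusion = occl
  ), class = "landmark_set")
}

#' Render a scene to an image and pixel-exact ground truth
#'
#' Deterministic given `params` (hair strokes and pixel noise are drawn
#' from `params$seed`). The iris mask is the iris disk clipped to the
#' palpebral fissure (between the lids); the eyebrow mask is the ideal
#' arc band, while the drawn hair strokes subsample it at `brow_density`,
#' emulating sparse-brow segmentation difficulty without giving up
#' analytic ground truth.
#'
#' @param params a `scene_params`.
#' @return list with `image` (H x W x 3 array in `[0, 1]`) and `truth`
#'   (list `iris_mask`, `brow_mask`, `landmarks`, `mm_per_px`).
#' @export
render_scene <- function(params) {
  validate_scene_params(params)
  h <- params$image_height; w <- params$image_width
  cx <- params$iris_center[1]; cy <- params$iris_center[2]
  r <- params$iris_radius
  xg <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  yg <- matrix(0:(h - 1L), h, w)
  xs <- 0:(w - 1L)
  yu <- matrix(poly_eval(params$upper_lid_curve, xs), h, w, byrow = TRUE)
  yl <- matrix(poly_eval(params$lower_lid_curve, xs), h, w, byrow = TRUE)
  yb <- matrix(poly_eval(params$brow_arc, xs), h, w, byrow = TRUE)
  between <- yg >= yu & yg <= yl
  disk <- (xg - cx)^2 + (yg - cy)^2 <= r^2
  iris_mask <- disk & between
  in_span <- xg >= params$brow_span[1] & xg <= params$brow_span[2]
  brow_mask <- in_span & abs(yg - yb) <= params$brow_thickness / 2
  if (any(brow_mask & iris_mask)) stop_input("brow and iris masks overlap")

  fissure <- between & abs(xg - cx) <= 1.35 * r & !disk
  pupil <- (xg - cx)^2 + (yg - cy)^2 <= (0.35 * r)^2 & between
  lid_line <- (abs(yg - yu) <= 1 | abs(yg - yl) <= 1) &
    abs(xg - cx) <= 1.45 * r

  img <- withr::with_seed(params$seed, {
    im <- array(0, dim = c(h, w, 3L))
    base <- matrix(rnorm(h * w, 0, params$noise_sd / 2), h, w)
    for (ch in 1:3) im[, , ch] <- params$skin_tone[ch] + base
    sclera <- c(0.96, 0.95, 0.93)
    iris_col <- c(0.30, 0.18, 0.10)
    pupil_col <- c(0.05, 0.05, 0.05)
    line_col <- params$skin_tone * 0.62
    hair_col <- c(0.22, 0.15, 0.10)
    # hair strokes: per-column vertical strokes subsampled at brow_density
    span_cols <- seq(ceiling(params$brow_span[1]), floor(params$brow_span[2]))
    stroked <- span_cols[runif(length(span_cols)) <= params$brow_density]
    jitter <- rnorm(length(stroked), 0, 0.06)
    stroke_mask <- matrix(FALSE, h, w)
    ybv <- poly_eval(params$brow_arc, stroked)
    half <- 0.45 * params$brow_thickness
    for (k in seq_along(stroked)) {
      rows <- seq(max(1L, round(ybv[k] - half * (1 + jitter[k])) + 1L),
                  min(h, round(ybv[k] + half * (1 - jitter[k])) + 1L))
      stroke_mask[rows, stroked[k] + 1L] <- TRUE
    }
    paint <- function(im, mask, col) {
      for (ch in 1:3) {
        plane <- im[, , ch]
        plane[mask] <- col[ch]
        im[, , ch] <- plane
      }
      im
    }
    im <- paint(im, lid_line, line_col)
    im <- paint(im, stroke_mask, hair_col)
    im <- paint(im, fissure, sclera)
    im <- paint(im, iris_mask, iris_col)
    im <- paint(im, pupil, pupil_col)
    im + array(rnorm(h * w * 3L, 0, params$noise_sd), dim = c(h, w, 3L))
  })
  list(
    image = clip01(img),
    truth = list(
      iris_mask = iris_mask,
      brow_mask = brow_mask,
      landmarks = ground_truth_landmarks(params),
      mm_per_px = 11 / (2 * r)
    )
  )
}

#' Generate a list of scenes in memory
#'
#' Convenience wrapper used by training and validation code: samples and
#' renders `n` scenes with independent child seeds.
#'
#' @param n number of scenes.
#' @param config a [scene_config()].
#' @param seed root seed; scene `i` uses a deterministic child seed.
#' @return list of `n` elements, each with `params`, `image`, `truth`.
#' @export
generate_scenes <- function(n, config = scene_config(), seed = 0L) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    params <- sample_scene_params(config, seed_child(seed, i))
    sc <- render_scene(params)
    list(params = params, image = sc$image, truth = sc$truth)
  })
}

#' Generate and persist a synthetic dataset
#'
#' Writes `n` scenes as PNG images plus iris/eyebrow mask PNGs and a
#' manifest CSV linking them to their analytic landmark ground truth.
#' Scenes assigned side `"right"` are stored horizontally mirrored,
#' emulating un-normalized right periocular photographs (the millimetre
#' ground truth is mirror-invariant). Re-running with identical arguments
#' reproduces identical files.
#'
#' @param n number of scenes (>= 1).
#' @param config a [scene_config()].
#' @param seed root seed.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly; also written to
#'   `dir/manifest.csv`.
#' @export
generate_dataset <- function(n, config = scene_config(), seed = 0L,
                             dir = "periomet-synthetic") {
  stopifnot(n >= 1)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop_input("cannot create output directory: ", dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    scene_seed <- seed_child(seed, i)
    params <- sample_scene_params(config, scene_seed)
    sc <- render_scene(params)
    side <- c("left", "right")[1L + seed_child(seed, n + i) %% 2L]
    img <- sc$image; iris <- sc$truth$iris_mask; brow <- sc$truth$brow_mask
    if (side == "right") {
      img <- img[, rev(seq_len(ncol(img))), , drop = FALSE]
      iris <- iris[, rev(seq_len(ncol(iris))), drop = FALSE]
      brow <- brow[, rev(seq_len(ncol(brow))), drop = FALSE]
    }
    id <- sprintf("scene_%04d", i)
    paths <- file.path(dir, paste0(c("img_", "iris_", "brow_"), id, ".png"))
    png::writePNG(img, paths[1])
    write_mask(iris, paths[2])
    write_mask(brow, paths[3])
    lm <- sc$truth$landmarks
    rows[[i]] <- data.frame(
      id = id, side = side,
      image_path = basename(paths[1]),
      iris_mask_path = basename(paths[2]),
      brow_mask_path = basename(paths[3]),
      mm_per_px = lm$mm_per_px,
      MRD1 = lm$mrd1_mm, MRD2 = lm$mrd2_mm,
      MBE = lm$brow_mm[["MBE"]], ML = lm$brow_mm[["ML"]],
      PC = lm$brow_mm[["PC"]], LL = lm$brow_mm[["LL"]],
      LBE = lm$brow_mm[["LBE"]],
      seed = scene_seed
    )
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
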