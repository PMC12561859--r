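## Mask -> landmark geometry.
##
## The measurement chain recovers the corneal outline from a (possibly
## lid-occluded) iris mask via the minimum enclosing circle, calibrates
## pixels to millimetres with the 11 mm corneal-diameter convention, and
## reads off seven landmarks: MRD1, MRD2 and eyebrow heights above the
## pupil-center baseline at the five columns MBE, ML, PC, LL, LBE.

CORNEAL_DIAMETER_MM <- 11.0

#' Largest 8-connected foreground component
#'
#' Robustness filter applied to predicted masks before geometry: speckle
#' false positives are dropped by keeping only the largest 8-connected
#' component. Ties in size are broken deterministically by the component
#' whose first foreground pixel in row-major order (top-to-bottom, then
#' left-to-right) comes first.
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @return logical matrix of the same size containing one component.
#' @export
largest_component <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop_input("empty mask: no foreground pixels")
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # row-major scan order = lexicographic (row, col): first pixel wins
    scan <- as.vector(t(lab))
    first_idx <- vapply(best, function(l) which(scan == l)[1L], integer(1))
    best <- best[which.min(first_idx)]
  }
  lab == best
}

# Run-length 8-connected component labeling with union-find.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  lab <- matrix(0L, h, w)
  prev_runs <- NULL  # matrix: start, end, label (runs of previous row)
  for (r in seq_len(h)) {
    row <- mask[r, ]
    if (!any(row)) { prev_runs <- NULL; next }
    d <- diff(c(FALSE, row, FALSE))
    starts <- which(d == 1L)
    ends <- which(d == -1L) - 1L
    labs <- integer(length(starts))
    for (k in seq_along(starts)) {
      lk <- 0L
      if (!is.null(prev_runs)) {
        # 8-connectivity: previous-row run touching [start-1, end+1]
        touch <- which(prev_runs[, 2L] >= starts[k] - 1L &
                       prev_runs[, 1L] <= ends[k] + 1L)
        for (t in touch) {
          rt <- find(prev_runs[t, 3L])
          if (lk == 0L) lk <- rt else if (rt != lk) parent[rt] <- find(lk)
        }
        if (lk != 0L) lk <- find(lk)
      }
      if (lk == 0L) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        lk <- length(parent)
      }
      labs[k] <- lk
      lab[r, starts[k]:ends[k]] <- lk
    }
    prev_runs <- cbind(starts, ends, labs)
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), find, integer(1))
    dense <- match(roots, sort(unique(roots)))
    nz <- lab > 0L
    lab[nz] <- dense[lab[nz]]
  }
  lab
}

#' Boundary pixels of a binary mask
#'
#' Foreground pixels with at least one 4-neighbor that is background (the
#' image border counts as background). The minimum enclosing circle of the
#' boundary equals that of the full foreground, so this is a lossless
#' input reduction for the circle solver.
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @return two-column matrix of 0-based `(x, y)` pixel-center coordinates.
#' @export
boundary_points <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop_input("empty mask: no foreground pixels")
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  up    <- pad[1:h, 2:(w + 1L)]
  down  <- pad[3:(h + 2L), 2:(w + 1L)]
  left  <- pad[2:(h + 1L), 1:w]
  right <- pad[2:(h + 1L), 3:(w + 2L)]
  bd <- core & !(up & down & left & right)
  idx <- which(bd, arr.ind = TRUE)
  cbind(x = idx[, "col"] - 1, y = idx[, "row"] - 1)
}

## ---- minimum enclosing circle -------------------------------------------

circle_obj <- function(center, radius) {
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "periomet_circle")
}

#' @export
print.periomet_circle <- function(x, ...) {
  cat(sprintf("circle: center (%.4f, %.4f), radius %.4f px\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

circle_contains <- function(circ, p, tol) {
  (p[1] - circ$center[1])^2 + (p[2] - circ$center[2])^2 <=
    (circ$radius + tol)^2
}

diameter_circle <- function(a, b) {
  circle_obj((a + b) / 2, sqrt(sum((a - b)^2)) / 2)
}

circumcircle <- function(a, b, c) {
  ox <- (min(a[1], b[1], c[1]) + max(a[1], b[1], c[1])) / 2
  oy <- (min(a[2], b[2], c[2]) + max(a[2], b[2], c[2])) / 2
  ax <- a[1] - ox; ay <- a[2] - oy
  bx <- b[1] - ox; by <- b[2] - oy
  cx <- c[1] - ox; cy <- c[2] - oy
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  x <- ox + ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
  y <- oy + ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
  circle_obj(c(x, y), sqrt((x - a[1])^2 + (y - a[2])^2))
}

cross2 <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

# Smallest circle with p and q on the boundary enclosing pts[1..n, ].
mec_two_fixed <- function(pts, p, q, tol) {
  circ <- diameter_circle(p, q)
  left <- NULL; right <- NULL
  lcross <- 0; rcross <- 0
  px <- p[1]; py <- p[2]; qx <- q[1]; qy <- q[2]
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, ]
    if (circle_contains(circ, r, tol)) next
    cr <- cross2(px, py, qx, qy, r[1], r[2])
    c3 <- circumcircle(p, q, r)
    if (is.null(c3)) next
    cc <- cross2(px, py, qx, qy, c3$center[1], c3$center[2])
    if (cr > 0 && (is.null(left) || cc > lcross)) {
      left <- c3; lcross <- cc
    } else if (cr < 0 && (is.null(right) || cc < rcross)) {
      right <- c3; rcross <- cc
    }
  }
  if (is.null(left) && is.null(right)) circ
  else if (is.null(left)) right
  else if (is.null(right)) left
  else if (left$radius <= right$radius) left else right
}

mec_one_fixed <- function(pts, p, tol) {
  circ <- diameter_circle(p, pts[1, ])
  for (i in seq_len(nrow(pts))[-1]) {
    if (!circle_contains(circ, pts[i, ], tol)) {
      circ <- mec_two_fixed(pts[seq_len(i - 1L), , drop = FALSE],
                            p, pts[i, ], tol)
    }
  }
  circ
}

#' Minimum enclosing circle (randomized incremental)
#'
#' Welzl-type expected-linear-time construction of the smallest circle
#' containing every input point. Applied to the visible-iris boundary it
#' recovers the full corneal outline even when the eyelids occlude part of
#' the iris, provided the horizontal extremes remain visible.
#'
#' The result is the unique minimum circle and therefore independent of
#' input order; points are shuffled internally (without disturbing the
#' caller's RNG state) only to guarantee the expected running time.
#'
#' @param points two-column matrix or data.frame of `(x, y)` coordinates.
#' @return a `periomet_circle`: list with `center` (x, y) and `radius`.
#' @seealso [min_enclosing_circle_bruteforce()] for the O(n^4) oracle.
#' @export
min_enclosing_circle <- function(points) {
  pts <- as.matrix(points)
  if (length(pts) == 0L || nrow(pts) < 1L) stop_input("need at least one point")
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n == 1L) return(circle_obj(pts[1, ], 0))
  scale <- max(1, max(abs(pts)))
  tol <- 1e-10 * scale
  perm <- withr::with_preserve_seed({
    set.seed(depth_seed_from(pts))
    sample.int(n)
  })
  pts <- pts[perm, , drop = FALSE]
  circ <- diameter_circle(pts[1, ], pts[2, ])
  if (n > 2L) {
    for (i in 3:n) {
      if (!circle_contains(circ, pts[i, ], tol)) {
        circ <- mec_one_fixed(pts[seq_len(i - 1L), , drop = FALSE],
                              pts[i, ], tol)
      }
    }
  }
  circ
}

# Deterministic shuffle seed derived from the point multiset (order
# independent) so identical point sets shuffle identically.
depth_seed_from <- function(pts) {
  s <- sum(pts[, 1]) * 7.31 + sum(pts[, 2]) * 3.17 + nrow(pts)
  as.integer(abs(s * 1000) %% 2147483629)
}

#' Brute-force minimum enclosing circle (test oracle)
#'
#' Exhaustive O(n^4) enumeration over all diameter (pair) circles and
#' circumcircles (triples), returning the smallest circle that contains
#' every point. Intended as an independent oracle for
#' [min_enclosing_circle()] on small inputs.
#'
#' @param points two-column matrix of `(x, y)` coordinates, `n <= 60`.
#' @return a `periomet_circle`.
#' @export
min_enclosing_circle_bruteforce <- function(points) {
  pts <- as.matrix(points)
  if (length(pts) == 0L || nrow(pts) < 1L) stop_input("need at least one point")
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n > 60L) stop_input("brute-force solver is limited to n <= 60 points")
  if (n == 1L) return(circle_obj(pts[1, ], 0))
  tol <- 1e-9 * max(1, max(abs(pts)))
  covers <- function(circ) {
    all((pts[, 1] - circ$center[1])^2 + (pts[, 2] - circ$center[2])^2 <=
          (circ$radius + tol)^2)
  }
  best <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    circ <- diameter_circle(pts[i, ], pts[j, ])
    if ((is.null(best) || circ$radius < best$radius) && covers(circ)) best <- circ
  }
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
      circ <- circumcircle(pts[i, ], pts[j, ], pts[k, ])
      if (!is.null(circ) && (is.null(best) || circ$radius < best$radius) &&
          covers(circ)) best <- circ
    }
  }
  best
}

## ---- calibration and landmarks ------------------------------------------

#' Calibrate the pixel grid against the 11 mm corneal diameter
#'
#' The horizontal corneal diameter is remarkably constant across adults
#' (~11 mm), so the diameter of the minimum enclosing circle of the iris
#' serves as an in-image scale bar: `mm_per_px = 11 / (2 * radius)`.
#'
#' @param circle a `periomet_circle` with positive radius.
#' @return list with `mm_per_px` and `reference_diameter_mm` (11).
#' @export
calibrate_scale <- function(circle) {
  if (!is.finite(circle$radius) || circle$radius <= 0) {
    stop_input("circle radius must be positive for calibration")
  }
  list(mm_per_px = CORNEAL_DIAMETER_MM / (2 * circle$radius),
       reference_diameter_mm = CORNEAL_DIAMETER_MM)
}

#' Landmark columns: MBE, ML, PC, LL, LBE
#'
#' The five measurement columns: pupil center (PC) at the circle center,
#' medial/lateral limbus (ML/LL) one radius to the medial/lateral side,
#' and the medial/lateral eyebrow ends (MBE/LBE) at the extreme occupied
#' columns of the eyebrow mask. Images are assumed normalized to
#' left-periocular framing, under which the medial (nasal) side is
#' image-left; pass `medial = "right"` for unnormalized right-side images.
#'
#' @param circle `periomet_circle` of the iris.
#' @param brow eyebrow mask (logical/0-1 matrix), non-empty.
#' @param medial which image side is medial: `"left"` (default) or `"right"`.
#' @return named integer vector of 0-based columns
#'   `c(MBE, ML, PC, LL, LBE)`.
#' @export
landmark_columns <- function(circle, brow, medial = c("left", "right")) {
  medial <- match.arg(medial)
  brow <- as_mask(brow)
  if (!any(brow)) stop_input("empty eyebrow mask")
  cx <- circle$center[1]; r <- circle$radius
  cols_occ <- range(which(colSums(brow) > 0L)) - 1L  # 0-based
  pc <- as.integer(round(cx))
  if (medial == "left") {
    ml <- as.integer(round(cx - r)); ll <- as.integer(round(cx + r))
    mbe <- cols_occ[1]; lbe <- cols_occ[2]
  } else {
    ml <- as.integer(round(cx + r)); ll <- as.integer(round(cx - r))
    mbe <- cols_occ[2]; lbe <- cols_occ[1]
  }
  c(MBE = mbe, ML = ml, PC = pc, LL = ll, LBE = lbe)
}

#' Eyebrow height above the pupil-center baseline at one column
#'
#' Height of the top of the eyebrow ("highest point" = smallest row index)
#' within a `2*band + 1` column window centred on `column`, measured
#' vertically from the pupil-center row and converted to millimetres.
#'
#' @param brow eyebrow mask.
#' @param column 0-based image column.
#' @param pupil_center numeric `(x, y)`, 0-based.
#' @param scale result of [calibrate_scale()].
#' @param band half-width of the column window in px (default 2).
#' @return list with `height_mm` (NA when no eyebrow pixel falls in the
#'   window) and `missing` flag.
#' @export
brow_height_at <- function(brow, column, pupil_center, scale, band = 2L) {
  brow <- as_mask(brow)
  if (!any(brow)) stop_input("empty eyebrow mask")
  lo <- max(0L, as.integer(column) - as.integer(band)) + 1L
  hi <- min(ncol(brow) - 1L, as.integer(column) + as.integer(band)) + 1L
  if (lo > hi) return(list(height_mm = NA_real_, missing = TRUE))
  sub <- brow[, lo:hi, drop = FALSE]
  if (!any(sub)) return(list(height_mm = NA_real_, missing = TRUE))
  top_row <- min(which(rowSums(sub) > 0L)) - 1L  # 0-based y
  list(height_mm = (pupil_center[2] - top_row) * scale$mm_per_px,
       missing = FALSE)
}

#' Margin reflex distances from the visible iris
#'
#' MRD1 (pupil center to upper lid margin) and MRD2 (pupil center to lower
#' lid margin) are read off the visible-iris extremal rows within a 3 px
#' column band at the pupil-center column. A mask-based measure cannot go
#' negative (lid margin below center), so raw negative values clip to 0;
#' occlusion flags record when the visible iris does not reach the circle
#' apex/base (i.e. the lid truncates the corneal outline).
#'
#' @param iris iris mask (visible part), non-empty.
#' @param circle minimum enclosing circle of the visible iris.
#' @param scale result of [calibrate_scale()].
#' @return list `mrd1_mm`, `mrd2_mm`, `occluded_top`, `occluded_bottom`.
#' @export
measure_mrd <- function(iris, circle, scale) {
  iris <- as_mask(iris)
  if (!any(iris)) stop_input("empty iris mask")
  cx <- circle$center[1]; cy <- circle$center[2]; r <- circle$radius
  pc_col <- as.integer(round(cx))
  lo <- max(0L, pc_col - 1L) + 1L
  hi <- min(ncol(iris) - 1L, pc_col + 1L) + 1L
  sub <- iris[, lo:hi, drop = FALSE]
  if (!any(sub)) stop_input("no iris pixels in the pupil-center column band")
  rows <- which(rowSums(sub) > 0L) - 1L  # 0-based y
  top <- min(rows); bottom <- max(rows)
  list(
    mrd1_mm = max(0, (cy - top) * scale$mm_per_px),
    mrd2_mm = max(0, (bottom - cy) * scale$mm_per_px),
    occluded_top = top > (cy - r) + 1,
    occluded_bottom = bottom < (cy + r) - 1
  )
}

#' Measure all seven periocular landmarks from a mask pair
#'
#' Full measurement chain: largest component filtering of both masks,
#' boundary extraction, minimum enclosing circle of the visible iris,
#' 11 mm calibration, landmark column derivation, eyebrow heights at the
#' five columns, and MRD1/MRD2.
#'
#' @param iris iris mask (matrix), non-empty.
#' @param brow eyebrow mask (matrix), non-empty.
#' @param medial medial image side, `"left"` (default) or `"right"`.
#' @param band column half-width for eyebrow heights (px, default 2).
#' @return a `landmark_set`: list with `mrd1_mm`, `mrd2_mm`, `brow_mm`
#'   (named vector MBE/ML/PC/LL/LBE), `columns_px`, `pupil_center`,
#'   `mm_per_px`, and `occlusion` flags.
#' @export
measure_all <- function(iris, brow, medial = c("left", "right"), band = 2L) {
  medial <- match.arg(medial)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_input(sprintf("measurement failed at stage '%s': %s",
                         name, conditionMessage(e)))
    })
  }
  iris_c <- stage("largest_component(iris)", largest_component(iris))
  brow_c <- stage("largest_component(brow)", largest_component(brow))
  bp <- stage("boundary_points", boundary_points(iris_c))
  circ <- stage("min_enclosing_circle", min_enclosing_circle(bp))
  scale <- stage("calibrate_scale", calibrate_scale(circ))
  cols <- stage("landmark_columns", landmark_columns(circ, brow_c, medial))
  heights <- lapply(cols, function(x) {
    brow_height_at(brow_c, x, circ$center, scale, band = band)
  })
  mrd <- stage("measure_mrd", measure_mrd(iris_c, circ, scale))
  brow_mm <- vapply(heights, `[[`, numeric(1), "height_mm")
  occl <- c(
    MRD1 = mrd$occluded_top, MRD2 = mrd$occluded_bottom,
    vapply(heights, `[[`, logical(1), "missing")
  )
  structure(list(
    mrd1_mm = mrd$mrd1_mm,
    mrd2_mm = mrd$mrd2_mm,
    brow_mm = brow_mm,
    columns_px = cols,
    pupil_center = circ$center,
    radius_px = circ$radius,
    mm_per_px = scale$mm_per_px,
    occlusion = occl
  ), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("MRD1 %.2f mm, MRD2 %.2f mm (scale %.4f mm/px)\n",
              x$mrd1_mm, x$mrd2_mm, x$mm_per_px))
  cat("brow heights (mm):\n")
  print(round(x$brow_mm, 2))
  invisible(x)
}

#' Flatten a landmark set to a one-row data.frame
#'
#' @param x a `landmark_set`.
#' @param ... unused.
#' @return one-row data.frame with columns `mrd1_mm`, `mrd2_mm`,
#'   `mbe_mm`, `ml_mm`, `pc_mm`, `ll_mm`, `lbe_mm`, `mm_per_px`,
#'   `occluded_top`, `occluded_bottom`.
#' @export
as.data.frame.landmark_set <- function(x, ...) {
  data.frame(
    mrd1_mm = x$mrd1_mm, mrd2_mm = x$mrd2_mm,
    mbe_mm = x$brow_mm[["MBE"]], ml_mm = x$brow_mm[["ML"]],
    pc_mm = x$brow_mm[["PC"]], ll_mm = x$brow_mm[["LL"]],
    lbe_mm = x$brow_mm[["LBE"]],
    mm_per_px = x$mm_per_px,
    occluded_top = x$occlusion[["MRD1"]],
    occluded_bottom = x$occlusion[["MRD2"]]
  )
}
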