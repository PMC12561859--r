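#' Evaluate a polynomial with intercept-first coefficients
#'
#' Horner evaluation of `c[1] + c[2]*x + c[3]*x^2 + ...`. Used for the
#' eyelid and eyebrow centerline curves, which map an image column x to a
#' row coordinate y.
#'
#' @param coefs numeric vector of coefficients, intercept first.
#' @param x numeric vector of evaluation points (image columns, px).
#' @return numeric vector of the same length as `x`.
#' @export
poly_eval <- function(coefs, x) {
  stopifnot(is.numeric(coefs), length(coefs) >= 1L)
  y <- rep(coefs[length(coefs)], length(x))
  if (length(coefs) > 1L) {
    for (k in seq(length(coefs) - 1L, 1L)) y <- y * x + coefs[k]
  }
  y
}

# Counter-based seed splitting: every scene/draw gets an independent,
# reproducible child seed derived from (root seed, counter). Kept below
# 2^31 - 1 so it is always a valid R integer.
seed_child <- function(seed, counter) {
  m <- 2147483629
  s <- (as.double(seed) %% m)
  for (k in c(counter + 1, 7919)) {
    s <- (s * 48271 + k * 9349 + 1) %% m
  }
  as.integer(s)
}

# Clip to [0, 1] preserving dims (pmax/pmin would drop them)
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Resize an RGB image (bilinear)
#'
#' Thin wrapper over [EBImage::resize()] used when feeding images to the
#' segmentation network. Masks are never resized with this; see
#' [resize_mask_nearest()].
#'
#' @param img H x W x 3 numeric array in `[0, 1]`.
#' @param size target side length in px (output is square `size x size`).
#' @return `size x size x 3` array.
#' @export
resize_rgb <- function(img, size) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  out <- EBImage::resize(img, w = size, h = size)
  out <- as.numeric(out)
  dim(out) <- c(size, size, 3L)
  clip01(out)
}

#' Resize a binary mask by nearest-neighbor sampling
#'
#' Deterministic nearest-neighbor resampling that preserves strict
#' binariness (no interpolated gray values).
#'
#' @param mask logical or 0/1 matrix.
#' @param size target side length in px.
#' @return logical `size x size` matrix.
#' @export
resize_mask_nearest <- function(mask, size) {
  mask <- as_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  ri <- pmin(h, pmax(1L, as.integer(round((seq_len(size) - 0.5) * h / size + 0.5))))
  ci <- pmin(w, pmax(1L, as.integer(round((seq_len(size) - 0.5) * w / size + 0.5))))
  mask[ri, ci, drop = FALSE]
}

# Coerce any 0/255, 0/1, or logical matrix to a logical mask, failing on
# genuinely non-binary content.
as_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  stopifnot(is.matrix(mask), is.numeric(mask))
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1) | u %in% c(0, 255))) {
    stop("mask is not binary (values other than 0/1 or 0/255 present)")
  }
  mask != 0
}

# Classed input-error condition so the CLI can map it to exit code 1.
stop_input <- function(...) {
  stop(structure(
    class = c("periomet_input_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
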