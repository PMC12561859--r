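## Gradient-based model inspection: input saliency and Grad-CAM.

resize_map_bilinear <- function(m, out_dim) {
  if (all(dim(m) == out_dim)) return(m)
  out <- EBImage::resize(m, w = out_dim[1], h = out_dim[2])
  out <- as.numeric(out)
  dim(out) <- out_dim
  out
}

#' Input saliency map
#'
#' Gradient of the summed foreground logit with respect to the input
#' pixels: the absolute gradient magnitude (maximum over the three color
#' channels), normalized so the maximum value is 1 (unless the gradient
#' is identically zero). Highlights the image regions that most
#' influence the model output.
#'
#' @param model a `seg_model`.
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @return H x W matrix in `[0, 1]` (the input image size).
#' @export
saliency_map <- function(model, image) {
  x <- image_to_tensor(image, model$input_size)
  out <- model_forward(model, x, keep_cache = TRUE)
  dlog <- array(1, dim(out$logits))  # d(sum of logits)/d(logit) = 1
  bk <- model_backward(model, out$cache, dlog)
  g <- abs(bk$dx)              # [3, hw, 1]
  mag <- apply(g[, , 1L, drop = TRUE], 2L, max)
  heat <- matrix(mag, model$input_size, model$input_size)
  heat <- resize_map_bilinear(heat, dim(image)[1:2])
  if (max(heat) > 0) heat <- heat / max(heat)
  clip01(heat)
}

#' Grad-CAM heatmap at a chosen network depth
#'
#' Class-activation mapping for the foreground class: channel weights are
#' the spatial means of the gradient of the summed foreground logit with
#' respect to the selected activation map; the weighted activation sum is
#' rectified, upsampled to the input size, and min-max normalized to
#' `[0, 1]`.
#'
#' @param model a `seg_model`.
#' @param image H x W x 3 RGB array.
#' @param layer activation to inspect: `"bottleneck"` (16 px),
#'   `"decoder_mid"` (32 px) or `"decoder_high"` (64 px; the deepest,
#'   highest-resolution decoder stage).
#' @return H x W matrix in `[0, 1]`.
#' @export
grad_cam <- function(model, image,
                     layer = c("decoder_high", "decoder_mid", "bottleneck")) {
  if (!layer[1] %in% c("decoder_high", "decoder_mid", "bottleneck")) {
    stop_input("unknown layer selector: ", layer[1])
  }
  layer <- layer[1]
  x <- image_to_tensor(image, model$input_size)
  out <- model_forward(model, x, keep_cache = TRUE)
  act <- switch(layer,
                bottleneck = out$cache$r4$y,
                decoder_mid = out$cache$rd2$y,
                decoder_high = out$cache$rd1$y)
  dlog <- array(1, dim(out$logits))
  bk <- model_backward(model, out$cache, dlog)
  dact <- bk$dact[[layer]]
  a <- act[, , 1L, drop = TRUE]    # [channels, pixels]
  g <- dact[, , 1L, drop = TRUE]
  if (is.null(dim(a))) { a <- matrix(a, 1L); g <- matrix(g, 1L) }
  wts <- rowMeans(g)
  cam <- pmax(0, colSums(a * wts))
  side <- as.integer(sqrt(length(cam)))
  heat <- resize_map_bilinear(matrix(cam, side, side), dim(image)[1:2])
  rng <- range(heat)
  if (diff(rng) > 0) heat <- (heat - rng[1]) / diff(rng)
  clip01(heat)
}

#' Measure model-only inference latency on CPU
#'
#' Times single-image forward passes only (no I/O, no preprocessing):
#' images are converted to input tensors before the clock starts, warm-up
#' passes are excluded, and per-image wall times are summarized as
#' mean/median/p90 in milliseconds.
#'
#' @param model a `seg_model`.
#' @param images list of H x W x 3 RGB arrays (>= 1).
#' @param threads advisory thread count recorded with the result; BLAS
#'   threading cannot be changed after load, so this is metadata only.
#' @param warmup untimed warm-up passes (default 5).
#' @return list `mean_ms`, `median_ms`, `p90_ms`, `n_images`, `threads`,
#'   `times_ms`.
#' @export
measure_latency <- function(model, images, threads = 1L, warmup = 5L) {
  if (length(images) < 1L) stop_input("need at least one image")
  xs <- lapply(images, image_to_tensor, input_size = model$input_size)
  for (k in seq_len(min(warmup, length(xs)))) {
    model_forward(model, xs[[k]])
  }
  times <- vapply(xs, function(x) {
    t0 <- proc.time()[["elapsed"]]
    model_forward(model, x)
    (proc.time()[["elapsed"]] - t0) * 1000
  }, numeric(1))
  list(
    mean_ms = mean(times),
    median_ms = median(times),
    p90_ms = unname(quantile(times, 0.9)),
    n_images = length(times),
    threads = as.integer(threads),
    times_ms = times
  )
}
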