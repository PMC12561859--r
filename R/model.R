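## U-Net-style binary segmentation model: a three-level convolutional
## encoder, a bottleneck, and a transpose-convolution decoder with skip
## connections, ending in a single-channel logit map at input resolution.

#' Training configuration
#'
#' Defaults follow the segmentation training recipe: batch size 16,
#' initial learning rate 0.005 with a reduce-on-plateau scheduler
#' (halved after 10 stagnant validation epochs), Adam optimization of a
#' binary cross-entropy-on-logits loss, 64 x 64 RGB inputs. The full
#' recipe runs for up to 1000 epochs; the default here is a desk-scale
#' profile.
#'
#' @param batch_size mini-batch size (>= 1).
#' @param max_epochs maximum training epochs.
#' @param initial_lr initial learning rate (> 0).
#' @param scheduler_patience stagnant epochs before a reduction.
#' @param scheduler_factor learning-rate reduction factor in `(0, 1)`.
#' @param min_delta strict-improvement tolerance for the scheduler.
#' @param input_size model input side length, px.
#' @param seed integer seed governing shuffling (and initialization when
#'   a model is built inside [train_model()]).
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 16L, max_epochs = 30L,
                         initial_lr = 0.005, scheduler_patience = 10L,
                         scheduler_factor = 0.5, min_delta = 1e-6,
                         input_size = 64L, seed = 0L) {
  stopifnot(batch_size >= 1, initial_lr > 0,
            scheduler_factor > 0, scheduler_factor < 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 initial_lr = initial_lr,
                 scheduler_patience = as.integer(scheduler_patience),
                 scheduler_factor = scheduler_factor,
                 min_delta = min_delta,
                 input_size = as.integer(input_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a segmentation model
#'
#' Constructs the network with seeded random (He) initialization:
#' encoder convolutions at 64/32/16 px with widths `width`, `2*width`,
#' `4*width`, a bottleneck, and a decoder using 2x2-stride-2 transposed
#' convolutions with skip concatenations, closed by a 1x1 convolution to
#' a single logit channel. Output spatial size equals input spatial
#' size. No pretrained weights are involved, so building is fully
#' offline and deterministic for a fixed seed.
#'
#' @param width base channel width (default 12).
#' @param input_size input side length, px (must be divisible by 4).
#' @param seed integer seed for weight initialization.
#' @return a `seg_model` list (parameters plus precomputed index maps).
#' @export
build_model <- function(width = 12L, input_size = 64L, seed = 0L) {
  stopifnot(input_size %% 4L == 0L, width >= 1L)
  w <- as.integer(width); s1 <- as.integer(input_size)
  s2 <- s1 %/% 2L; s3 <- s1 %/% 4L
  params <- withr::with_seed(as.integer(seed %% 2147483647), list(
    stem = init_conv3(3L, w),
    enc2 = init_conv3(w, 2L * w),
    enc3 = init_conv3(2L * w, 4L * w),
    bott = init_conv3(4L * w, 4L * w),
    up2 = init_upconv(4L * w, 2L * w),
    dec2 = init_conv3(4L * w, 2L * w),
    up1 = init_upconv(2L * w, w),
    dec1 = init_conv3(2L * w, w),
    head = init_conv1(w, 1L)
  ))
  geom <- list(
    s1 = s1, s2 = s2, s3 = s3,
    pool1 = make_pool_maps(s1, s1),
    pool2 = make_pool_maps(s2, s2),
    up_from3 = make_up_maps(s3, s3),
    up_from2 = make_up_maps(s2, s2)
  )
  structure(list(params = params, width = w, input_size = s1, geom = geom,
                 seed = as.integer(seed)),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("seg_model: width %d, input %dx%d, %d parameters\n",
              x$width, x$input_size, x$input_size, n_par))
  invisible(x)
}

# Forward pass. x: [3, s1^2, batch]. Returns logits and (optionally) the
# cache needed for the backward pass.
model_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params; g <- model$geom
  c1 <- conv3_forward(x, p$stem, g$s1, g$s1); r1 <- relu_forward(c1$y)
  pl1 <- pool_forward(r1$y, g$pool1)
  c2 <- conv3_forward(pl1$y, p$enc2, g$s2, g$s2); r2 <- relu_forward(c2$y)
  pl2 <- pool_forward(r2$y, g$pool2)
  c3 <- conv3_forward(pl2$y, p$enc3, g$s3, g$s3); r3 <- relu_forward(c3$y)
  c4 <- conv3_forward(r3$y, p$bott, g$s3, g$s3); r4 <- relu_forward(c4$y)
  u2 <- upconv_forward(r4$y, p$up2, g$up_from3)
  cat2 <- concat_channels(u2$y, r2$y)
  d2 <- conv3_forward(cat2, p$dec2, g$s2, g$s2); rd2 <- relu_forward(d2$y)
  u1 <- upconv_forward(rd2$y, p$up1, g$up_from2)
  cat1 <- concat_channels(u1$y, r1$y)
  d1 <- conv3_forward(cat1, p$dec1, g$s1, g$s1); rd1 <- relu_forward(d1$y)
  hd <- conv1_forward(rd1$y, p$head)
  out <- list(logits = hd$y)
  if (keep_cache) {
    out$cache <- list(c1 = c1, r1 = r1, pl1 = pl1, c2 = c2, r2 = r2,
                      pl2 = pl2, c3 = c3, r3 = r3, c4 = c4, r4 = r4,
                      u2 = u2, d2 = d2, rd2 = rd2, u1 = u1, d1 = d1,
                      rd1 = rd1, hd = hd)
  }
  out
}

# Backward pass from d(logits); returns parameter gradients, the input
# gradient, and gradients at the tagged activations used by Grad-CAM.
model_backward <- function(model, cache, dlogits) {
  p <- model$params; g <- model$geom
  grads <- list()
  bk <- conv1_backward(dlogits, cache$hd, p$head); grads$head <- bk[c("dW", "db")]
  d_rd1 <- bk$dx
  d_d1 <- d_rd1 * cache$rd1$m
  bk <- conv3_backward(d_d1, cache$d1, p$dec1, g$s1, g$s1)
  grads$dec1 <- bk[c("dW", "db")]
  w <- model$width
  d_u1 <- bk$dx[seq_len(w), , , drop = FALSE]
  d_r1_skip <- bk$dx[w + seq_len(w), , , drop = FALSE]
  bk <- upconv_backward(d_u1, cache$u1, p$up1, g$up_from2)
  grads$up1 <- bk[c("dW", "db")]
  d_rd2 <- bk$dx
  d_d2 <- d_rd2 * cache$rd2$m
  bk <- conv3_backward(d_d2, cache$d2, p$dec2, g$s2, g$s2)
  grads$dec2 <- bk[c("dW", "db")]
  d_u2 <- bk$dx[seq_len(2L * w), , , drop = FALSE]
  d_r2_skip <- bk$dx[2L * w + seq_len(2L * w), , , drop = FALSE]
  bk <- upconv_backward(d_u2, cache$u2, p$up2, g$up_from3)
  grads$up2 <- bk[c("dW", "db")]
  d_r4 <- bk$dx
  d_c4 <- d_r4 * cache$r4$m
  bk <- conv3_backward(d_c4, cache$c4, p$bott, g$s3, g$s3)
  grads$bott <- bk[c("dW", "db")]
  d_r3 <- bk$dx
  d_c3 <- d_r3 * cache$r3$m
  bk <- conv3_backward(d_c3, cache$c3, p$enc3, g$s3, g$s3)
  grads$enc3 <- bk[c("dW", "db")]
  d_pl2 <- bk$dx
  d_r2 <- pool_backward(d_pl2, cache$pl2, g$pool2, g$s2^2) + d_r2_skip
  d_c2 <- d_r2 * cache$r2$m
  bk <- conv3_backward(d_c2, cache$c2, p$enc2, g$s2, g$s2)
  grads$enc2 <- bk[c("dW", "db")]
  d_pl1 <- bk$dx
  d_r1 <- pool_backward(d_pl1, cache$pl1, g$pool1, g$s1^2) + d_r1_skip
  d_c1 <- d_r1 * cache$r1$m
  bk <- conv3_backward(d_c1, cache$c1, p$stem, g$s1, g$s1)
  grads$stem <- bk[c("dW", "db")]
  # rename gradient fields to match parameter layout (W, b)
  grads <- lapply(grads, function(gr) list(W = gr$dW, b = gr$db))
  grads <- grads[names(model$params)]
  list(grads = grads, dx = bk$dx,
       dact = list(bottleneck = d_r4, decoder_mid = d_rd2,
                   decoder_high = d_rd1))
}

#' Convert rendered scenes to training tensors
#'
#' Resizes scene images (bilinear) and ground-truth masks
#' (nearest-neighbor) to the model input size and stacks them in the
#' engine's channels-first layout.
#'
#' @param scenes list from [generate_scenes()].
#' @param task which mask is the target: `"iris"` or `"brow"`.
#' @param input_size model input side length.
#' @return list with `x` `[3, input_size^2, n]` and `y`
#'   `[1, input_size^2, n]`.
#' @export
scenes_to_tensors <- function(scenes, task = c("iris", "brow"),
                              input_size = 64L) {
  task <- match.arg(task)
  n <- length(scenes)
  hw <- input_size^2
  x <- array(0, c(3L, hw, n))
  y <- array(0, c(1L, hw, n))
  key <- if (task == "iris") "iris_mask" else "brow_mask"
  for (i in seq_len(n)) {
    img <- resize_rgb(scenes[[i]]$image, input_size)
    for (ch in 1:3) x[ch, , i] <- as.vector(img[, , ch])
    y[1L, , i] <- as.vector(resize_mask_nearest(scenes[[i]]$truth[[key]],
                                                input_size)) * 1.0
  }
  list(x = x, y = y)
}

eval_loss <- function(model, x, y, chunk = 32L) {
  n <- dim(x)[3]
  total <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    out <- model_forward(model, x[, , idx, drop = FALSE])
    l <- bce_with_logits(out$logits, y[, , idx, drop = FALSE])
    total <- total + l$loss * length(idx)
  }
  total / n
}

#' Train a segmentation model
#'
#' Mini-batch Adam on binary cross-entropy-with-logits, with a
#' reduce-on-plateau learning-rate schedule and best-validation-loss
#' checkpointing (the returned model carries the parameters of the epoch
#' with the lowest validation loss). Fully deterministic for a fixed
#' `(model, data, config)`.
#'
#' @param model a `seg_model` from [build_model()].
#' @param train_data,val_data tensor lists from [scenes_to_tensors()];
#'   both non-empty.
#' @param config a [train_config()].
#' @return list with `model` (best-validation parameters) and `history`
#'   (data.frame epoch/train_loss/val_loss/lr).
#' @export
train_model <- function(model, train_data, val_data, config = train_config()) {
  n_train <- dim(train_data$x)[3]
  n_val <- dim(val_data$x)[3]
  if (is.null(n_train) || n_train < 1L) stop_input("empty training set")
  if (is.null(n_val) || n_val < 1L) stop_input("empty validation set")
  sched <- plateau_scheduler(config$initial_lr, config$scheduler_patience,
                             config$scheduler_factor, config$min_delta)
  opt <- adam_init(model$params)
  best_params <- model$params
  best_val <- Inf
  hist <- vector("list", config$max_epochs)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n_train)
      epoch_loss <- 0
      for (s in seq(1L, n_train, by = config$batch_size)) {
        idx <- perm[s:min(n_train, s + config$batch_size - 1L)]
        xb <- train_data$x[, , idx, drop = FALSE]
        yb <- train_data$y[, , idx, drop = FALSE]
        out <- model_forward(model, xb, keep_cache = TRUE)
        l <- bce_with_logits(out$logits, yb)
        if (!is.finite(l$loss)) {
          stop_input("non-finite training loss at epoch ", epoch)
        }
        epoch_loss <- epoch_loss + l$loss * length(idx)
        bk <- model_backward(model, out$cache, l$grad)
        upd <- adam_step(model$params, bk$grads, opt, sched$lr)
        model$params <- upd$params
        opt <- upd$state
      }
      train_loss <- epoch_loss / n_train
      val_loss <- eval_loss(model, val_data$x, val_data$y)
      if (!is.finite(val_loss)) {
        stop_input("non-finite validation loss at epoch ", epoch)
      }
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- model$params
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss, lr = sched$lr)
      sched <- scheduler_step(sched, val_loss)
    }
  })
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist))
}

image_to_tensor <- function(image, input_size) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop_input("input image must be an RGB (H x W x 3) array")
  }
  img <- if (all(dim(image)[1:2] == input_size)) image else
    resize_rgb(image, input_size)
  x <- array(0, c(3L, input_size^2, 1L))
  for (ch in 1:3) x[ch, , 1L] <- as.vector(img[, , ch])
  x
}

#' Predict a binary mask for an image
#'
#' Resizes the image to the model input, applies the network, converts
#' logits to probabilities with the sigmoid, thresholds, and (by default)
#' upscales the mask back to the original image size by nearest-neighbor.
#'
#' @param model a `seg_model`.
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @param threshold probability threshold for foreground (default 0.5).
#' @param upscale return the mask at the original image size (default
#'   TRUE); the probability map is always at model resolution.
#' @return list with `prob` (input_size x input_size matrix in `[0, 1]`)
#'   and `mask` (logical matrix).
#' @export
predict_mask <- function(model, image, threshold = 0.5, upscale = TRUE) {
  x <- image_to_tensor(image, model$input_size)
  out <- model_forward(model, x)
  prob <- matrix(stats::plogis(as.vector(out$logits)),
                 model$input_size, model$input_size)
  mask <- prob >= threshold
  if (upscale && !all(dim(image)[1:2] == model$input_size)) {
    mask <- upscale_mask_nearest(mask, dim(image)[1:2])
  }
  list(prob = prob, mask = mask)
}

upscale_mask_nearest <- function(mask, out_dim) {
  ri <- pmin(nrow(mask), pmax(1L, as.integer(
    round((seq_len(out_dim[1]) - 0.5) * nrow(mask) / out_dim[1] + 0.5))))
  ci <- pmin(ncol(mask), pmax(1L, as.integer(
    round((seq_len(out_dim[2]) - 0.5) * ncol(mask) / out_dim[2] + 0.5))))
  mask[ri, ci, drop = FALSE]
}

#' Save / load a model checkpoint
#'
#' Single-file serialization of parameters plus the training
#' configuration and seed used to produce them.
#'
#' @param model a `seg_model`.
#' @param config the `train_config` used (optional).
#' @param path checkpoint file path.
#' @return (load) the restored `seg_model` with attribute
#'   `train_config`.
#' @export
save_checkpoint <- function(model, path, config = NULL) {
  saveRDS(list(params = model$params, width = model$width,
               input_size = model$input_size, seed = model$seed,
               config = config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_input("checkpoint not found: ", path)
  ck <- readRDS(path)
  model <- build_model(width = ck$width, input_size = ck$input_size,
                       seed = ck$seed)
  model$params <- ck$params
  attr(model, "train_config") <- ck$config
  model
}
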