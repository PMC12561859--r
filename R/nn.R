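## Native R neural-network engine for the segmentation models.
##
## Feature maps are stored as arrays [channels, pixels, batch] with
## pixels in column-major (row-fastest) order for a square grid. A 3x3
## convolution is computed as nine channel-mixing matrix products over
## shifted copies of the input, so all heavy lifting is BLAS GEMM; the
## backward passes are the exact adjoints. This keeps training fully
## deterministic for a fixed seed.

# 2x2 max-pool index quadruple (input pixel indices per output pixel).
make_pool_maps <- function(h, w) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  r <- rep(seq_len(h2), times = w2) * 2L
  c <- rep(seq_len(w2), each = h2) * 2L
  list(
    i00 = (c - 2L) * h + (r - 1L), i10 = (c - 2L) * h + r,
    i01 = (c - 1L) * h + (r - 1L), i11 = (c - 1L) * h + r
  )
}

# 2x2-stride-2 transposed-convolution output index quadruple: each input
# pixel (r, c) populates the 2x2 output block at (2r-1, 2c-1).
make_up_maps <- function(h, w) {
  h2 <- 2L * h
  r <- rep(seq_len(h), times = w)
  c <- rep(seq_len(w), each = h)
  list(
    o00 = (2L * c - 2L) * h2 + (2L * r - 1L),
    o10 = (2L * c - 2L) * h2 + 2L * r,
    o01 = (2L * c - 1L) * h2 + (2L * r - 1L),
    o11 = (2L * c - 1L) * h2 + 2L * r
  )
}

# 3x3 convolution, zero-padded, stride 1: compiled im2col + GEMM.
conv3_forward <- function(x, layer, h, w) {
  y <- conv3_fwd_cpp(x, layer$W, layer$b, h, w)
  list(y = y, x = x)
}

conv3_backward <- function(dy, cache, layer, h, w) {
  bk <- conv3_bwd_cpp(dy, cache$x, layer$W, h, w)
  list(dx = bk$dx, dW = bk$dW, db = as.vector(bk$db))
}

conv1_forward <- function(x, layer) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3])
  y <- layer$W %*% xm + layer$b
  dim(y) <- c(nrow(layer$W), d[2], d[3])
  list(y = y, x = x)
}

conv1_backward <- function(dy, cache, layer) {
  d <- dim(dy)
  dym <- dy; dim(dym) <- c(d[1], d[2] * d[3])
  xm <- cache$x; dx_in <- dim(cache$x)
  dim(xm) <- c(dx_in[1], dx_in[2] * dx_in[3])
  dx <- t(layer$W) %*% dym
  dim(dx) <- dx_in
  list(dx = dx, dW = dym %*% t(xm), db = rowSums(dym))
}

pool_forward <- function(x, pm) {
  x00 <- x[, pm$i00, , drop = FALSE]; x10 <- x[, pm$i10, , drop = FALSE]
  x01 <- x[, pm$i01, , drop = FALSE]; x11 <- x[, pm$i11, , drop = FALSE]
  y <- pmax(pmax(x00, x10), pmax(x01, x11))
  list(y = y, x00 = x00, x10 = x10, x01 = x01, x11 = x11)
}

pool_backward <- function(dy, cache, pm, hw_in) {
  y <- pmax(pmax(cache$x00, cache$x10), pmax(cache$x01, cache$x11))
  m00 <- cache$x00 == y
  m10 <- cache$x10 == y & !m00
  m01 <- cache$x01 == y & !(m00 | m10)
  m11 <- !(m00 | m10 | m01)
  d <- dim(dy)
  dx <- array(0, c(d[1], hw_in, d[3]))
  dx[, pm$i00, ] <- dy * m00
  dx[, pm$i10, ] <- dx[, pm$i10, , drop = FALSE] + dy * m10
  dx[, pm$i01, ] <- dx[, pm$i01, , drop = FALSE] + dy * m01
  dx[, pm$i11, ] <- dx[, pm$i11, , drop = FALSE] + dy * m11
  dx
}

upconv_forward <- function(x, layer, um) {
  d <- dim(x); cin <- d[1]; hw <- d[2]; b <- d[3]
  cout <- nrow(layer$W[[1]])
  xm <- x; dim(xm) <- c(cin, hw * b)
  y <- array(0, c(cout, 4L * hw, b))
  keys <- c("o00", "o10", "o01", "o11")
  for (k in 1:4) {
    yk <- layer$W[[k]] %*% xm
    dim(yk) <- c(cout, hw, b)
    y[, um[[keys[k]]], ] <- yk
  }
  y <- y + array(rep(layer$b, times = 4L * hw * b), dim(y))
  list(y = y, xm = xm, dims = d)
}

upconv_backward <- function(dy, cache, layer, um) {
  cin <- cache$dims[1]; hw <- cache$dims[2]; b <- cache$dims[3]
  keys <- c("o00", "o10", "o01", "o11")
  dW <- vector("list", 4L)
  dxm <- matrix(0, cin, hw * b)
  dym_all <- 0
  for (k in 1:4) {
    dyk <- dy[, um[[keys[k]]], , drop = FALSE]
    dim(dyk) <- c(dim(dy)[1], hw * b)
    dW[[k]] <- dyk %*% t(cache$xm)
    dxm <- dxm + t(layer$W[[k]]) %*% dyk
    dym_all <- dym_all + rowSums(dyk)
  }
  dx <- dxm; dim(dx) <- cache$dims
  list(dx = dx, dW = dW, db = dym_all)
}

relu_forward <- function(x) {
  m <- x > 0
  list(y = x * m, m = m)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1] + db[1], da[2], da[3]))
  y[seq_len(da[1]), , ] <- a
  y[da[1] + seq_len(db[1]), , ] <- b
  y
}

# Binary cross-entropy on logits, numerically stable; mean reduction.
bce_with_logits <- function(z, t) {
  zv <- as.vector(z); tv <- as.vector(t)
  loss <- mean(pmax(zv, 0) - zv * tv + log1p(exp(-abs(zv))))
  grad <- (stats::plogis(zv) - tv) / length(zv)
  dim(grad) <- dim(z)
  list(loss = loss, grad = grad)
}

## ---- parameter init and Adam --------------------------------------------

he_mat <- function(cout, cin, k2) {
  matrix(rnorm(cout * cin, 0, sqrt(2 / (cin * k2))), cout, cin)
}

init_conv3 <- function(cin, cout) {
  # single [cout, 9*cin] matrix; fan-in = 9 * cin
  list(W = he_mat(cout, 9L * cin, 1L), b = numeric(cout))
}

init_conv1 <- function(cin, cout) {
  list(W = he_mat(cout, cin, 1), b = numeric(cout))
}

init_upconv <- function(cin, cout) {
  list(W = lapply(1:4, function(i) he_mat(cout, cin, 4)), b = numeric(cout))
}

# Elementwise map over two parallel nested lists of numeric leaves.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) {
    out <- mapply(function(x, y, z) tree_map3(f, x, y, z), a, b, c,
                  SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b, c)
  }
}

adam_init <- function(params) {
  zero <- function(x, y) x * 0
  list(m = tree_map2(zero, params, params),
       v = tree_map2(zero, params, params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map3(function(p, m, v) p - lr * (m / bc1) /
                        (sqrt(v / bc2) + eps),
                      params, state$m, state$v)
  list(params = params, state = state)
}

## ---- plateau learning-rate scheduler -------------------------------------

#' Reduce-on-plateau learning-rate scheduler
#'
#' Halves (by `factor`) the learning rate when the validation loss has
#' not improved for `patience` consecutive epochs; "improvement" means a
#' strict decrease by more than `min_delta`. The stagnation counter
#' resets after each reduction.
#'
#' @param initial_lr starting learning rate.
#' @param patience stagnant epochs tolerated before a reduction.
#' @param factor multiplicative reduction factor in `(0, 1)`.
#' @param min_delta improvement tolerance.
#' @return scheduler state list; advance it with [scheduler_step()].
#' @export
plateau_scheduler <- function(initial_lr = 0.005, patience = 10L,
                              factor = 0.5, min_delta = 1e-6) {
  stopifnot(initial_lr > 0, factor > 0, factor < 1, patience >= 1)
  list(lr = initial_lr, best = Inf, wait = 0L,
       patience = as.integer(patience), factor = factor,
       min_delta = min_delta)
}

#' Advance the plateau scheduler by one epoch
#'
#' @param state scheduler state from [plateau_scheduler()].
#' @param val_loss the epoch's validation loss.
#' @return updated state (fields `lr`, `best`, `wait`).
#' @export
scheduler_step <- function(state, val_loss) {
  if (val_loss < state$best - state$min_delta) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr * state$factor
      state$wait <- 0L
    }
  }
  state
}
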