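# Shared fixtures, generated in code. Scenes are cached per helper session
# so several test files can reuse the same renders.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(seed) {
  key <- as.character(seed)
  if (is.null(.scene_cache[[key]])) {
    params <- sample_scene_params(scene_config(), seed = seed)
    .scene_cache[[key]] <- c(list(params = params), render_scene(params))
  }
  .scene_cache[[key]]
}

# rasterized disk mask with integer center/radius (exact reference shapes)
disk_mask <- function(h, w, cx, cy, r) {
  xg <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  yg <- matrix(0:(h - 1L), h, w)
  (xg - cx)^2 + (yg - cy)^2 <= r^2
}

# random blob: union of a few random disks (always non-empty)
random_blob <- function(h = 40L, w = 40L, n_disks = 3L) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(n_disks)) {
    m <- m | disk_mask(h, w, runif(1, 8, w - 8), runif(1, 8, h - 8),
                       runif(1, 2, 6))
  }
  m
}

circles_equal <- function(a, b, tol = 1e-7) {
  abs(a$radius - b$radius) < tol && all(abs(a$center - b$center) < tol)
}

# A small iris model trained once per test session, reused by the
# prediction-quality and heatmap-localization tests.
trained_iris_model <- function() {
  if (is.null(.scene_cache$toy_model)) {
    scenes <- generate_scenes(72, scene_config(), seed = 4040)
    d <- scenes_to_tensors(scenes[1:64], "iris")
    v <- scenes_to_tensors(scenes[65:72], "iris")
    fit <- train_model(build_model(width = 6, seed = 4040), d, v,
                       train_config(max_epochs = 25, seed = 4040))
    .scene_cache$toy_model <- fit$model
  }
  .scene_cache$toy_model
}

# mean heatmap intensity inside the dilated iris region minus outside
iris_heat_contrast <- function(heat, iris_mask) {
  inside <- EBImage::dilate(iris_mask * 1, EBImage::makeBrush(15, "box")) > 0
  mean(heat[inside]) - mean(heat[!inside])
}
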