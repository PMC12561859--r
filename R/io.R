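## Dataset I/O, side normalization, and splitting.

#' Read a binary mask from a PNG file
#'
#' Any nonzero value reads as foreground; grayscale and RGB(A) PNGs are
#' accepted (a pixel is foreground when any channel is nonzero).
#'
#' @param path PNG file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_input("mask file not found: ", path)
  px <- tryCatch(png::readPNG(path),
                 error = function(e) stop_input("not a readable PNG: ", path))
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), max)
  if (length(dim(px)) != 2L) stop_input("mask is not a 2-D image: ", path)
  px != 0
}

#' Write a binary mask to an 8-bit PNG (0/255)
#'
#' @param mask logical or 0/1 matrix.
#' @param path output PNG path.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read an RGB image from a PNG or JPEG-free pipeline PNG
#'
#' @param path PNG file path.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_input("image file not found: ", path)
  px <- tryCatch(png::readPNG(path),
                 error = function(e) stop_input("not a readable PNG: ", path))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  px
}

#' Normalize a right-side periocular image to left framing
#'
#' Right periocular inputs are mirrored about the vertical axis so that
#' all downstream processing sees a consistent left-periocular framing
#' (medial side on image-left); left inputs pass through unchanged.
#' Masks are flipped consistently with the image.
#'
#' @param image H x W x 3 array (or NULL).
#' @param masks named list of mask matrices (or NULL).
#' @param side `"left"` or `"right"`.
#' @return list with `image` and `masks`, left-oriented.
#' @export
normalize_side <- function(image = NULL, masks = NULL,
                           side = c("left", "right")) {
  if (!is.character(side) || !side[1] %in% c("left", "right")) {
    stop_input("side must be \"left\" or \"right\"")
  }
  side <- side[1]
  fliph <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(dim(x)) == 3L) x[, rev(seq_len(ncol(x))), , drop = FALSE]
    else x[, rev(seq_len(ncol(x))), drop = FALSE]
  }
  if (side == "left") return(list(image = image, masks = masks))
  list(image = fliph(image), masks = lapply(masks, fliph))
}

#' Load a dataset manifest CSV
#'
#' @param path manifest CSV (schema of [generate_dataset()]).
#' @param check_files verify that referenced files exist (default TRUE).
#' @return data.frame of dataset items.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop_input("manifest not found: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "side", "image_path", "iris_mask_path", "brow_mask_path")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop_input("manifest lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(man$id)) stop_input("duplicate ids in manifest")
  if (check_files) {
    base <- dirname(path)
    for (col in c("image_path", "iris_mask_path", "brow_mask_path")) {
      full <- file.path(base, man[[col]])
      bad <- !file.exists(full)
      if (any(bad)) stop_input("missing file referenced by manifest: ",
                               full[which(bad)[1]])
    }
  }
  man
}

#' Split a dataset into train/validation/test subsets
#'
#' Subset sizes are the floors of `n * ratios`; leftover items are then
#' assigned one at a time in the order train, test, val (612 items at
#' 0.8/0.1/0.1 give 490/61/61). Assignment is a deterministic function of
#' the seed. With `group_by`, all items sharing a group value stay in one
#' subset and the allocation operates on groups.
#'
#' @param items data.frame of dataset items (e.g. a manifest).
#' @param ratios numeric `(train, val, test)` summing to 1.
#' @param seed integer seed.
#' @param group_by optional column name (e.g. patient id) for grouped
#'   splitting.
#' @return `items` with a `split` column (`"train"`, `"val"`, `"test"`).
#' @export
split_dataset <- function(items, ratios = c(0.8, 0.1, 0.1), seed = 0L,
                          group_by = NULL) {
  if (abs(sum(ratios) - 1) > 1e-9) stop_input("ratios must sum to 1")
  if (length(ratios) != 3L || any(ratios < 0)) {
    stop_input("ratios must be three non-negative numbers")
  }
  units <- if (is.null(group_by)) seq_len(nrow(items)) else {
    if (!group_by %in% names(items)) stop_input("unknown group column: ",
                                                group_by)
    unique(items[[group_by]])
  }
  n <- length(units)
  if (n < 3L) stop_input("need at least three ",
                         if (is.null(group_by)) "items" else "groups")
  counts <- floor(n * ratios)
  leftover <- n - sum(counts)
  # leftover priority: train, then test, then val (matches 612 -> 490/61/61)
  for (k in c(1L, 3L, 2L)) {
    if (leftover == 0L) break
    counts[k] <- counts[k] + 1L
    leftover <- leftover - 1L
  }
  if (any(counts == 0L)) {
    warning("degenerate split: at least one subset is empty", call. = FALSE)
  }
  perm <- withr::with_seed(as.integer(seed %% 2147483647), sample.int(n))
  assign_unit <- rep(c("train", "val", "test"), times = counts)
  unit_split <- setNames(assign_unit[order(perm)], units)
  # order(perm) scatters the block assignment randomly over units
  items$split <- if (is.null(group_by)) {
    unname(unit_split[as.character(seq_len(nrow(items)))])
  } else {
    unname(unit_split[as.character(items[[group_by]])])
  }
  items
}

#' Save an error report to CSV (and JSON)
#'
#' Writes the per-landmark table with overall summary rows appended; a
#' JSON sidecar carries the full report including exclusion counts.
#'
#' @param report an `error_report` from [landmark_error_report()].
#' @param path output CSV path (`.json` sidecar written next to it).
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "error_report"))
  df <- report$per_landmark
  extra <- data.frame(
    landmark = c("overall_mean", "brow_subgroup_mean"),
    rmse_mm = c(report$overall_rmse_mm, report$brow_rmse_mm),
    mape_pct = c(report$overall_mape_pct, report$brow_mape_pct),
    n = NA_integer_, n_excluded = NA_integer_
  )
  write.csv(rbind(df, extra), path, row.names = FALSE)
  jsonlite::write_json(unclass(report),
                       sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
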