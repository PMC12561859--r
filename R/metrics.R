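## Segmentation and landmark-accuracy metrics.

#' Pixelwise confusion counts between a predicted and a true mask
#'
#' @param predicted,truth masks (logical/0-1 matrices) on identical frames.
#' @return list with `tp`, `fp`, `tn`, `fn` pixel counts.
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- as_mask(predicted); truth <- as_mask(truth)
  if (!identical(dim(predicted), dim(truth))) {
    stop_input("predicted and truth masks have different frames")
  }
  list(
    tp = sum(predicted & truth),
    fp = sum(predicted & !truth),
    tn = sum(!predicted & !truth),
    fn = sum(!predicted & truth)
  )
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy (TP+TN)/total, precision TP/(TP+FP), recall (sensitivity)
#' TP/(TP+FN), F1 = 2*precision*recall/(precision+recall) and
#' IoU = TP/(TP+FP+FN). A ratio with zero denominator is reported as
#' `NA` (undefined), never silently as 0 or 1, so degenerate masks stay
#' visible in reports.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (see
#'   [confusion_counts()]).
#' @return named list `accuracy`, `precision`, `recall`, `f1`, `iou`.
#' @export
seg_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fp + tn + fn
  if (total == 0) stop_input("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(
    accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f1 = f1,
    iou = ratio(tp, tp + fp + fn)
  )
}

#' Mean absolute percentage error
#'
#' `(100/n) * sum(|actual - predicted| / |actual|)`, in percent. The
#' denominator is always the reference ("actual") value, matching the
#' formula's asymmetry.
#'
#' @param actual,predicted equal-length numeric vectors; no actual value
#'   may be zero.
#' @return MAPE in percent.
#' @export
mape <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop_input("length mismatch")
  if (length(actual) < 1L) stop_input("need at least one value")
  zero <- which(actual == 0)
  if (length(zero)) {
    stop_input("MAPE undefined: actual value is zero at index ", zero[1L])
  }
  100 / length(actual) * sum(abs(actual - predicted) / abs(actual))
}

#' Root mean square error
#'
#' `sqrt(mean((actual - predicted)^2))`, in the units of the inputs.
#'
#' @param actual,predicted equal-length numeric vectors.
#' @return RMSE.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop_input("length mismatch")
  if (length(actual) < 1L) stop_input("need at least one value")
  sqrt(sum((actual - predicted)^2) / length(actual))
}

LANDMARK_NAMES <- c("MRD1", "MRD2", "MBE", "ML", "PC", "LL", "LBE")
BROW_LANDMARKS <- c("MBE", "ML", "PC", "LL", "LBE")

landmark_frame_cols <- c(MRD1 = "mrd1_mm", MRD2 = "mrd2_mm", MBE = "mbe_mm",
                         ML = "ml_mm", PC = "pc_mm", LL = "ll_mm",
                         LBE = "lbe_mm")

#' Per-landmark RMSE/MAPE error report
#'
#' Aggregates paired automated and reference measurements into a
#' per-landmark table of RMSE (mm) and MAPE (%) plus overall summaries.
#' Overall values are unweighted arithmetic means of the per-landmark
#' values (not pooled over all pairs); the brow subgroup mean averages the
#' five eyebrow landmarks (MBE, ML, PC, LL, LBE). Pairs where either side
#' is `NA` (occluded/missing landmark) are excluded per landmark, with
#' exclusion counts reported.
#'
#' @param predicted,truth data.frames with columns `mrd1_mm`, `mrd2_mm`,
#'   `mbe_mm`, `ml_mm`, `pc_mm`, `ll_mm`, `lbe_mm` (one row per image;
#'   rows paired by position), or lists of `landmark_set` objects.
#' @return an `error_report`: list with `per_landmark` data.frame
#'   (landmark, rmse_mm, mape_pct, n, n_excluded), `overall_rmse_mm`,
#'   `overall_mape_pct`, `brow_mape_pct`, `brow_rmse_mm`.
#' @export
landmark_error_report <- function(predicted, truth) {
  to_frame <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, as.data.frame))
  }
  pred <- to_frame(predicted); tru <- to_frame(truth)
  if (nrow(pred) != nrow(tru)) stop_input("paired lists of unequal length")
  if (nrow(pred) < 1L) stop_input("need at least one measurement pair")
  rows <- lapply(LANDMARK_NAMES, function(lm) {
    col <- landmark_frame_cols[[lm]]
    a <- tru[[col]]; p <- pred[[col]]
    keep <- is.finite(a) & is.finite(p)
    if (!any(keep)) {
      stop_input("no valid pairs remain for landmark ", lm,
                 " after exclusions")
    }
    data.frame(
      landmark = lm,
      rmse_mm = rmse(a[keep], p[keep]),
      mape_pct = mape(a[keep], p[keep]),
      n = sum(keep),
      n_excluded = sum(!keep)
    )
  })
  per <- do.call(rbind, rows)
  brow <- per[per$landmark %in% BROW_LANDMARKS, ]
  structure(list(
    per_landmark = per,
    overall_rmse_mm = mean(per$rmse_mm),
    overall_mape_pct = mean(per$mape_pct),
    brow_rmse_mm = mean(brow$rmse_mm),
    brow_mape_pct = mean(brow$mape_pct)
  ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  df <- x$per_landmark
  df$rmse_mm <- round(df$rmse_mm, 3)
  df$mape_pct <- round(df$mape_pct, 2)
  print(df, row.names = FALSE)
  cat(sprintf("overall: RMSE %.2f mm, MAPE %.2f%% (brow subgroup MAPE %.2f%%)\n",
              x$overall_rmse_mm, x$overall_mape_pct, x$brow_mape_pct))
  invisible(x)
}

#' Aggregate an already-computed per-landmark error table
#'
#' Convenience entry for re-aggregating published or externally computed
#' per-landmark RMSE/MAPE values with the same unweighted-mean convention
#' as [landmark_error_report()].
#'
#' @param per_landmark data.frame with columns `landmark`, `rmse_mm`,
#'   `mape_pct` covering the seven landmarks.
#' @return list `overall_rmse_mm`, `overall_mape_pct`, `brow_rmse_mm`,
#'   `brow_mape_pct`.
#' @export
aggregate_landmark_errors <- function(per_landmark) {
  stopifnot(all(c("landmark", "rmse_mm", "mape_pct") %in% names(per_landmark)))
  missing <- setdiff(LANDMARK_NAMES, per_landmark$landmark)
  if (length(missing)) stop_input("missing landmarks: ",
                                  paste(missing, collapse = ", "))
  brow <- per_landmark[per_landmark$landmark %in% BROW_LANDMARKS, ]
  list(
    overall_rmse_mm = mean(per_landmark$rmse_mm),
    overall_mape_pct = mean(per_landmark$mape_pct),
    brow_rmse_mm = mean(brow$rmse_mm),
    brow_mape_pct = mean(brow$mape_pct)
  )
}
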