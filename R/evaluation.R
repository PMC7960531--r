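#' Delineation accuracy against a ground-truth mask
#'
#' True positive, false negative and false positive areas of a delineated
#' region, expressed as percentages of the ground-truth area (so
#' `tp_pct + fn_pct = 100` exactly, and `fp_pct` is unbounded above), plus
#' the raw areas in mm^2.
#'
#' @param pred_mask,truth_mask Logical matrices of equal shape; the truth
#'   mask must be nonempty.
#' @param mm_per_px Image scale for the mm^2 areas.
#' @param fp_denominator `"truth"` (default) divides the false-positive
#'   area by the ground-truth area; `"pred"` by the delineated area.
#' @return An `area_metrics` list: `tp_pct`, `fn_pct`, `fp_pct`,
#'   `areas_mm2` (named `tp`, `fn`, `fp`), `mm_per_px`.
#' @export
area_metrics <- function(pred_mask, truth_mask, mm_per_px = 1,
                         fp_denominator = c("truth", "pred")) {
  fp_denominator <- match.arg(fp_denominator)
  if (!all(dim(pred_mask) == dim(truth_mask))) {
    stop("masks must share one shape", call. = FALSE)
  }
  pred <- as.logical(pred_mask); truth <- as.logical(truth_mask)
  n_truth <- sum(truth)
  if (n_truth == 0) stop("ground-truth mask is empty", call. = FALSE)
  tp <- sum(pred & truth)
  fn <- sum(truth & !pred)
  fp <- sum(pred & !truth)
  fp_den <- if (fp_denominator == "truth") n_truth else max(1L, sum(pred))
  structure(
    list(tp_pct = 100 * tp / n_truth,
         fn_pct = 100 * fn / n_truth,
         fp_pct = 100 * fp / fp_den,
         areas_mm2 = c(tp = tp, fn = fn, fp = fp) * mm_per_px^2,
         mm_per_px = mm_per_px),
    class = "area_metrics")
}

#' @export
print.area_metrics <- function(x, ...) {
  cat(sprintf("<area_metrics> TP %.1f%% / FN %.1f%% / FP %.1f%% of ground-truth area\n",
              x$tp_pct, x$fn_pct, x$fp_pct))
  invisible(x)
}

#' Probe-tip tracking error against ground truth
#'
#' Per-frame Euclidean distance between tracked and true tip coordinates,
#' converted to mm with the ground-truth scale. Frames the tracker flagged
#' invalid (marker misses, occlusion) are excluded from the statistics and
#' counted separately.
#'
#' @param pose_table Output of [track_video()].
#' @param truth_table Ground-truth table from [generate_probe_video()]
#'   (columns `tipx`, `tipy`; occluded frames may be marked in `occluded`).
#' @param mm_per_px_truth True image scale.
#' @return A `tracking_error_stats` list: `mean_mm`, `sd_mm`,
#'   `per_frame_mm` (NA on invalid frames), `n_valid_frames`,
#'   `n_invalid_frames`.
#' @export
tracking_error <- function(pose_table, truth_table, mm_per_px_truth) {
  if (nrow(pose_table) != nrow(truth_table)) {
    stop("pose and truth tables must cover the same frames", call. = FALSE)
  }
  err_px <- sqrt((pose_table$tipx - truth_table$tipx)^2 +
                 (pose_table$tipy - truth_table$tipy)^2)
  err_mm <- err_px * mm_per_px_truth
  valid <- pose_table$valid & is.finite(err_mm)
  if (!any(valid)) stop("no valid frames to evaluate", call. = FALSE)
  per_frame <- ifelse(valid, err_mm, NA_real_)
  structure(
    list(mean_mm = mean(err_mm[valid]),
         sd_mm = if (sum(valid) > 1) stats::sd(err_mm[valid]) else 0,
         per_frame_mm = per_frame,
         n_valid_frames = sum(valid),
         n_invalid_frames = sum(!valid)),
    class = "tracking_error_stats")
}

#' @export
print.tracking_error_stats <- function(x, ...) {
  cat(sprintf("<tracking_error_stats> mean %.3f +/- %.3f mm over %d valid frames (%d invalid)\n",
              x$mean_mm, x$sd_mm, x$n_valid_frames, x$n_invalid_frames))
  invisible(x)
}

#' Delineation accuracy across a sweep of safety margins
#'
#' Runs [build_boundary()] + [area_metrics()] once per margin. Because a
#' larger margin only grows the delineated region, both `tp_pct` and
#' `fp_pct` are non-decreasing in the margin — the sensitivity/specificity
#' trade-off a clinician tunes with the margin setting.
#'
#' @param positives Positive tip coordinates (matrix/data frame, x then y).
#' @param truth_mask Ground-truth lesion mask.
#' @param margins_mm Non-negative margins to evaluate (mm).
#' @param mm_per_px Image scale.
#' @param tip_diameter_mm Passed to [build_boundary()].
#' @param fp_denominator Passed to [area_metrics()].
#' @return Data frame with one row per margin: `margin_mm`, `tp_pct`,
#'   `fn_pct`, `fp_pct`, `tp_mm2`, `fn_mm2`, `fp_mm2`.
#' @export
margin_sweep_report <- function(positives, truth_mask, margins_mm,
                                mm_per_px, tip_diameter_mm = 0,
                                fp_denominator = "truth") {
  if (any(margins_mm < 0)) stop("margins must be non-negative", call. = FALSE)
  rows <- lapply(margins_mm, function(m) {
    res <- build_boundary(positives, m, mm_per_px, dim(truth_mask),
                          tip_diameter_mm = tip_diameter_mm)
    am <- area_metrics(res$mask, truth_mask, mm_per_px,
                       fp_denominator = fp_denominator)
    data.frame(margin_mm = m, tp_pct = am$tp_pct, fn_pct = am$fn_pct,
               fp_pct = am$fp_pct,
               tp_mm2 = am$areas_mm2[["tp"]], fn_mm2 = am$areas_mm2[["fn"]],
               fp_mm2 = am$areas_mm2[["fp"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
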