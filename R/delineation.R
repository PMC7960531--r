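#' Diagnosis store
#'
#' Append-only record of spatial diagnoses: each accepted acquisition gets
#' the next 1-based index (the order number displayed in the overlay), the
#' tracked tip coordinate, the predicted label/score/positive flag, and the
#' frame's mm-per-px scale. Margin delineation is a pure function of this
#' store, so temporary probe occlusion never loses past measurements.
#'
#' @return An empty `diagnosis_store`.
#' @export
diagnosis_store <- function() {
  structure(list(records = data.frame(
    index = integer(0), tipx = numeric(0), tipy = numeric(0),
    label = character(0), score = numeric(0), positive = logical(0),
    mm_per_px = numeric(0), stringsAsFactors = FALSE)),
    class = "diagnosis_store")
}

#' @export
print.diagnosis_store <- function(x, ...) {
  cat(sprintf("<diagnosis_store> %d acquisitions (%d positive)\n",
              nrow(x$records), sum(x$records$positive)))
  invisible(x)
}

#' Record one diagnosis at the tracked tip
#'
#' @param store A [diagnosis_store()].
#' @param pose A valid `probe_pose` (see [estimate_tip()]); invalid poses
#'   are rejected with a warning and leave the store unchanged.
#' @param diag A `diagnosis` (see [predict.plsda_model()]).
#' @return The updated store.
#' @export
add_diagnosis <- function(store, pose, diag) {
  stopifnot(inherits(store, "diagnosis_store"))
  if (!isTRUE(pose$valid)) {
    warning("invalid probe pose: diagnosis not recorded", call. = FALSE)
    return(store)
  }
  score <- if (!is.null(names(diag$scores))) {
    # score of the predicted class
    unname(diag$scores[diag$label])
  } else max(diag$scores)
  rec <- data.frame(
    index = nrow(store$records) + 1L,
    tipx = pose$tip_px[1], tipy = pose$tip_px[2],
    label = diag$label, score = score, positive = isTRUE(diag$positive),
    mm_per_px = pose$mm_per_px, stringsAsFactors = FALSE)
  store$records <- rbind(store$records, rec)
  store
}

#' Read / write a diagnosis store as CSV
#'
#' @param store A [diagnosis_store()].
#' @param path File path.
#' @return `write_store_csv` returns `path` invisibly; `read_store_csv`
#'   returns a reconstructed [diagnosis_store()].
#' @export
write_store_csv <- function(store, path) {
  utils::write.csv(store$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_store_csv
#' @export
read_store_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  st <- diagnosis_store()
  st$records <- d
  st
}

# ---- convex geometry helpers -------------------------------------------

# hull vertices in counter-clockwise order (in the x-right / y-down frame
# convention the numeric orientation is irrelevant; we fix sign by area)
hull_ccw <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) <= 2L) return(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  h <- pts[idx, , drop = FALSE]
  x <- h[, 1]; y <- h[, 2]
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  h
}

# distance from points (px, py) to the convex hull of `pts` (0 inside)
dist_to_convex <- function(px, py, pts) {
  hull <- hull_ccw(pts)
  n <- nrow(hull)
  if (n == 1L) {
    return(sqrt((px - hull[1, 1])^2 + (py - hull[1, 2])^2))
  }
  seg_dist <- function(a, b) {
    vx <- b[1] - a[1]; vy <- b[2] - a[2]
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - a[1]) * vx + (py - a[2]) * vy) / L2))
    sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
  }
  if (n == 2L) return(seg_dist(hull[1, ], hull[2, ]))
  d <- rep(Inf, length(px))
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[if (i == n) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & cross >= -1e-9
    d <- pmin(d, seg_dist(a, b))
  }
  d[inside] <- 0
  d
}

# sampled boundary of the convex hull buffered outward by r (>= 0):
# support-function sampling, exact for convex sets; duplicate vertices
# collapsed
buffered_boundary <- function(pts, r, n_theta = 720L) {
  hull <- hull_ccw(pts)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  ct <- cos(theta); st <- sin(theta)
  sup <- hull[, 1, drop = TRUE] %o% ct + hull[, 2, drop = TRUE] %o% st
  best <- max.col(t(sup), ties.method = "first")
  bx <- hull[best, 1] + r * ct
  by <- hull[best, 2] + r * st
  keep <- c(TRUE, abs(diff(bx)) > 1e-9 | abs(diff(by)) > 1e-9)
  cbind(x = bx[keep], y = by[keep])
}

#' Build the lesion boundary with a safety margin
#'
#' Positive diagnosis locations are connected into a boundary (their
#' convex hull) and expanded outward by the safety margin plus, by
#' default's caller choice, half the probe tip diameter: 0 positives give
#' an empty result, 1 a disk, 2 a capsule, and 3 or more a buffered hull.
#' The mask rasterizes the expanded region with half-open pixel coverage
#' (a pixel is inside iff its center is), clipped to the frame.
#'
#' @param positives Matrix/data frame of positive tip coordinates
#'   (`x`, `y` in pixels); may have zero rows.
#' @param margin_mm Safety margin (>= 0, mm).
#' @param mm_per_px Positive image scale.
#' @param frame_shape `c(height, width)` of the output mask.
#' @param tip_diameter_mm Probe tip diameter whose radius is added to the
#'   buffer (default 0 for pure point geometry).
#' @return A `delineation_result`: `boundary` (sampled polygon, or `NULL`
#'   when empty), `mask` (logical matrix), `margin_mm`, `mm_per_px`.
#' @export
build_boundary <- function(positives, margin_mm, mm_per_px, frame_shape,
                           tip_diameter_mm = 0) {
  if (mm_per_px <= 0) stop("mm_per_px must be positive", call. = FALSE)
  if (margin_mm < 0) stop("margin_mm must be >= 0", call. = FALSE)
  pts <- as.matrix(as.data.frame(positives))[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  h <- frame_shape[1]; w <- frame_shape[2]
  res <- structure(list(boundary = NULL,
                        mask = matrix(FALSE, h, w),
                        margin_mm = margin_mm, mm_per_px = mm_per_px),
                   class = "delineation_result")
  if (nrow(pts) == 0) return(res)
  r_px <- (margin_mm + tip_diameter_mm / 2) / mm_per_px
  px <- rep(seq_len(w), each = h)
  py <- rep(seq_len(h), times = w)
  d <- dist_to_convex(px, py, pts)
  res$mask <- matrix(d <= r_px, h, w)
  res$boundary <- buffered_boundary(pts, r_px)
  res
}

#' Suggest next measurement locations
#'
#' Candidate acquisition sites are placed on the current boundary offset
#' outward by `spacing_mm`, at arc-length intervals of about `spacing_mm`,
#' excluding locations within `spacing_mm` of any existing measurement
#' (positive or negative) — the automated analog of a clinician choosing
#' where to probe next around a growing lesion outline.
#'
#' @param store A [diagnosis_store()] with at least one positive (an empty
#'   candidate list is returned otherwise).
#' @param spacing_mm Positive spacing (mm).
#' @param mm_per_px Image scale; defaults to the median of the per-
#'   acquisition scales in the store.
#' @return Matrix of candidate `(x, y)` pixel coordinates (possibly empty).
#' @export
suggest_points <- function(store, spacing_mm, mm_per_px = NULL) {
  stopifnot(inherits(store, "diagnosis_store"))
  if (spacing_mm <= 0) stop("spacing_mm must be positive", call. = FALSE)
  rec <- store$records
  pos <- rec[rec$positive, c("tipx", "tipy"), drop = FALSE]
  if (nrow(pos) == 0) return(cbind(x = numeric(0), y = numeric(0)))
  if (is.null(mm_per_px)) mm_per_px <- stats::median(rec$mm_per_px)
  spacing_px <- spacing_mm / mm_per_px
  ring <- buffered_boundary(as.matrix(pos), spacing_px, n_theta = 1440L)
  closed <- rbind(ring, ring[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  L <- sum(seg)
  n_cand <- max(1L, round(L / spacing_px))
  targets <- (seq_len(n_cand) - 1L) * L / n_cand
  cum <- c(0, cumsum(seg))
  interp <- function(d) {
    i <- findInterval(d, cum, rightmost.closed = TRUE)
    i <- min(i, length(seg))
    t <- if (seg[i] == 0) 0 else (d - cum[i]) / seg[i]
    closed[i, ] * (1 - t) + closed[i + 1, ] * t
  }
  cand <- t(vapply(targets, interp, numeric(2)))
  colnames(cand) <- c("x", "y")
  # drop candidates close to any existing measurement
  all_pts <- as.matrix(rec[, c("tipx", "tipy")])
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    min(sqrt((all_pts[, 1] - cand[i, 1])^2 +
             (all_pts[, 2] - cand[i, 2])^2)) >= spacing_px
  }, logical(1))
  cand[keep, , drop = FALSE]
}

# ---- overlay rendering --------------------------------------------------

# 3x5 bitmap digit font for acquisition order numbers
digit_font <- function() {
  rows <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"))
  lapply(rows, function(r) {
    do.call(rbind, lapply(r, function(s) as.integer(strsplit(s, "")[[1]]) == 1))
  })
}

set_pixels <- function(frame, rows, cols, rgb) {
  d <- dim(frame)
  ok <- rows >= 1 & rows <= d[1] & cols >= 1 & cols <= d[2]
  rows <- rows[ok]; cols <- cols[ok]
  for (ch in 1:3) {
    frame[cbind(rows, cols, ch)] <- rgb[ch]
  }
  frame
}

draw_number <- function(frame, number, center, rgb) {
  font <- digit_font()
  digits <- strsplit(as.character(number), "")[[1]]
  width <- 4L * length(digits) - 1L
  x0 <- round(center[1] - width / 2)
  y0 <- round(center[2] - 2)
  for (k in seq_along(digits)) {
    bm <- font[[digits[k]]]
    idx <- which(bm, arr.ind = TRUE)
    frame <- set_pixels(frame, y0 + idx[, 1] - 1L,
                        x0 + (k - 1L) * 4L + idx[, 2] - 1L, rgb)
  }
  frame
}

draw_square <- function(frame, center, half, rgb) {
  rows <- round(center[2]) + (-half:half)
  cols <- round(center[1]) + (-half:half)
  grid <- expand.grid(r = rows, c = cols)
  set_pixels(frame, grid$r, grid$c, rgb)
}

draw_polyline <- function(frame, poly, rgb) {
  closed <- rbind(poly, poly[1, ])
  for (i in seq_len(nrow(poly))) {
    a <- closed[i, ]; b <- closed[i + 1, ]
    n <- max(2L, ceiling(2 * sqrt(sum((b - a)^2))))
    t <- seq(0, 1, length.out = n)
    frame <- set_pixels(frame, round(a[2] + t * (b[2] - a[2])),
                        round(a[1] + t * (b[1] - a[1])), rgb)
  }
  frame
}

#' Render the augmented-reality overlay
#'
#' Draws every recorded acquisition onto the frame — green squares for
#' negative diagnoses, red for positive, each carrying its acquisition
#' order number — plus the delineated lesion boundary as a red polyline.
#' Rendering is deterministic: identical inputs give bit-identical images.
#'
#' @param frame Color frame array.
#' @param store A [diagnosis_store()].
#' @param result Optional `delineation_result` whose boundary to draw.
#' @param square_half Half-width of the diagnosis squares in pixels.
#' @return Annotated frame array.
#' @export
render_overlay <- function(frame, store, result = NULL, square_half = 5L) {
  stopifnot(inherits(store, "diagnosis_store"))
  green <- c(0, 0.8, 0); red <- c(1, 0, 0); white <- c(1, 1, 1)
  out <- frame
  if (!is.null(result) && !is.null(result$boundary)) {
    out <- draw_polyline(out, result$boundary, red)
  }
  rec <- store$records
  for (i in seq_len(nrow(rec))) {
    col <- if (rec$positive[i]) red else green
    center <- c(rec$tipx[i], rec$tipy[i])
    out <- draw_square(out, center, square_half, col)
    out <- draw_number(out, rec$index[i], center, white)
  }
  out
}

#' Threshold-based fluorescence delineation
#'
#' The comparison arm of the margin study: delineates the lesion directly
#' from a wide-field fluorescence image by intensity thresholding, either
#' at a fixed value or at an automatic bimodal (Otsu) threshold.
#'
#' @param image Single-channel numeric matrix.
#' @param threshold_mode `"fixed"` or `"auto"`.
#' @param threshold_value Threshold intensity for `"fixed"` mode.
#' @return Logical mask, `image >= threshold`.
#' @export
fluorescence_delineation <- function(image,
                                     threshold_mode = c("fixed", "auto"),
                                     threshold_value = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (!is.matrix(image)) stop("image must be a single-channel matrix", call. = FALSE)
  thr <- if (threshold_mode == "fixed") {
    if (is.null(threshold_value)) {
      stop("threshold_value required in fixed mode", call. = FALSE)
    }
    threshold_value
  } else {
    otsu_threshold(image)
  }
  image >= thr
}

# Otsu threshold on a 256-bin histogram; errors on a flat image where no
# bimodal split exists
otsu_threshold <- function(image, n_bins = 256L) {
  rng <- range(image)
  if (diff(rng) < .Machine$double.eps) {
    stop("flat image: no bimodal threshold exists", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(image, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- 0
  breaks[which.max(between) + 1L]
}
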