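#' @title Coordinate convention
#' @description Frames are numeric arrays `[row, col, channel]` with values
#' in `[0, 1]`. Points are `(x, y)` with `x` the column index (rightward)
#' and `y` the row index (downward), 1-based pixel centers, origin at the
#' top-left pixel.
#' @name frame-coordinates
#' @keywords internal
NULL

#' Fiducial marker color specification
#'
#' HSV window that defines one colored fiducial marker: a tolerance around
#' a hue center (degrees, treated circularly so red markers straddling 0
#' degrees work), minimum saturation and value, and a minimum blob area
#' below which a detection is reported as a miss.
#'
#' @param name Marker name; the probe geometry identifies markers by name
#'   (`"proximal"`, `"distal"`), so identity is fixed by color, not
#'   position.
#' @param hue_center Hue in `[0, 360)` degrees.
#' @param hue_tol Half-width of the hue window (degrees).
#' @param sat_min,val_min Minimum saturation / value in `[0, 1]`.
#' @param min_area_px Detection floor (connected-component pixel count).
#' @return An object of class `marker_spec`.
#' @export
marker_spec <- function(name, hue_center, hue_tol = 18, sat_min = 0.35,
                        val_min = 0.2, min_area_px = 20) {
  if (hue_center < 0 || hue_center >= 360) {
    stop("hue_center must lie in [0, 360)", call. = FALSE)
  }
  if (hue_tol <= 0) stop("hue_tol must be positive", call. = FALSE)
  structure(list(name = as.character(name), hue_center = hue_center,
                 hue_tol = hue_tol, sat_min = sat_min, val_min = val_min,
                 min_area_px = min_area_px),
            class = "marker_spec")
}

#' Probe geometry
#'
#' A-priori physical geometry of the probe: two colinear fiducial markers
#' and the measurement tip on their common axis. Together with the pixel
#' distance between detected marker centroids this fixes the image scale
#' per frame, so the tip can be extrapolated ratiometrically.
#'
#' @param marker_separation_mm Distance between the two marker centers (mm).
#' @param tip_offset_mm Distance from the distal marker center to the probe
#'   tip along the probe axis (mm).
#' @param tip_diameter_mm Physical tip diameter (default 2.1 mm); a
#'   measurement senses a disk of this width, which margin delineation can
#'   fold into its buffer radius.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(marker_separation_mm = 20, tip_offset_mm = 30,
                           tip_diameter_mm = 2.1) {
  if (marker_separation_mm <= 0 || tip_offset_mm < 0 || tip_diameter_mm <= 0) {
    stop("geometry distances must be positive (tip offset >= 0)", call. = FALSE)
  }
  structure(list(marker_separation_mm = marker_separation_mm,
                 tip_offset_mm = tip_offset_mm,
                 tip_diameter_mm = tip_diameter_mm),
            class = "probe_geometry")
}

# circular distance between hues, in degrees, in [0, 180]
hue_distance <- function(h1, h2) {
  d <- abs(h1 - h2) %% 360
  pmin(d, 360 - d)
}

# frame array -> list of h (degrees), s, v matrices
frame_hsv <- function(frame) {
  stopifnot(length(dim(frame)) == 3L, dim(frame)[3] >= 3L)
  d <- dim(frame)
  m <- rbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
             as.vector(frame[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' Calibrate marker HSV windows from seed pixels
#'
#' The tracking workflow starts with one manual identification per marker:
#' a single pixel inside each marker region. Statistics of a small square
#' neighborhood around each seed give the HSV window — circular-mean hue,
#' and 5th-percentile saturation/value minus a slack.
#'
#' @param frame Color frame array (see package coordinate convention).
#' @param seed_points Named list of `(x, y)` pixels, one per marker, e.g.
#'   `list(proximal = c(120, 200), distal = c(160, 200))`.
#' @param halfwidth Neighborhood half-width in pixels (default 3, a 7x7
#'   patch).
#' @param hue_tol Hue tolerance given to each resulting [marker_spec()].
#' @param slack Subtracted from the 5th-percentile saturation and value.
#' @param min_area_px Passed through to each [marker_spec()].
#' @return Named list of [marker_spec()] objects (same names as
#'   `seed_points`).
#' @export
calibrate_hsv <- function(frame, seed_points, halfwidth = 3L, hue_tol = 18,
                          slack = 0.1, min_area_px = 20) {
  stopifnot(is.list(seed_points), length(seed_points) >= 2L,
            !is.null(names(seed_points)))
  hsv <- frame_hsv(frame)
  d <- dim(frame)
  specs <- list()
  for (nm in names(seed_points)) {
    p <- seed_points[[nm]]
    cx <- round(p[1]); cy <- round(p[2])
    rows <- max(1, cy - halfwidth):min(d[1], cy + halfwidth)
    cols <- max(1, cx - halfwidth):min(d[2], cx + halfwidth)
    h <- hsv$h[rows, cols]; s <- hsv$s[rows, cols]; v <- hsv$v[rows, cols]
    if (stats::median(s) < 0.2) {
      stop(sprintf(
        "seed for '%s' lies on a low-saturation region (median S = %.2f); place it inside the marker",
        nm, stats::median(s)), call. = FALSE)
    }
    # circular mean hue so windows straddling 0 degrees calibrate correctly
    ang <- h * pi / 180
    hue_center <- (atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi) %% 360
    specs[[nm]] <- marker_spec(
      nm, hue_center = hue_center, hue_tol = hue_tol,
      sat_min = max(0.05, stats::quantile(s, 0.05) - slack),
      val_min = max(0.05, stats::quantile(v, 0.05) - slack),
      min_area_px = min_area_px
    )
  }
  centers <- vapply(specs, `[[`, 0, "hue_center")
  tols <- vapply(specs, `[[`, 0, "hue_tol")
  for (i in seq_along(specs)) {
    for (j in seq_along(specs)) {
      if (i < j && hue_distance(centers[i], centers[j]) <= tols[i] + tols[j]) {
        stop(sprintf("hue windows of '%s' and '%s' overlap; markers are not distinguishable",
                     names(specs)[i], names(specs)[j]), call. = FALSE)
      }
    }
  }
  specs
}

#' Segment fiducial markers in one frame
#'
#' For each marker spec: pixels within the circular hue tolerance with
#' saturation and value above the minima form a binary mask; a 3x3
#' morphological opening then closing removes speckle; the largest
#' connected component gives the detection, with its unweighted pixel
#' centroid. Components below `min_area_px` are misses — misses are data,
#' not errors.
#'
#' @param frame Color frame array.
#' @param specs List of [marker_spec()] objects.
#' @return Data frame with one row per spec: `name`, `found`, `cx`, `cy`,
#'   `area`.
#' @export
segment_markers <- function(frame, specs) {
  hsv <- frame_hsv(frame)
  brush <- EBImage::makeBrush(3, shape = "box")
  out <- lapply(specs, function(sp) {
    mask <- hue_distance(hsv$h, sp$hue_center) <= sp$hue_tol &
      hsv$s >= sp$sat_min & hsv$v >= sp$val_min
    mask <- EBImage::closing(EBImage::opening(mask * 1, brush), brush)
    lab <- EBImage::bwlabel(mask)
    n_obj <- max(lab)
    if (n_obj == 0) {
      return(data.frame(name = sp$name, found = FALSE, cx = NA_real_,
                        cy = NA_real_, area = 0))
    }
    sizes <- tabulate(lab[lab > 0], nbins = n_obj)
    best <- which.max(sizes)
    if (sizes[best] < sp$min_area_px) {
      return(data.frame(name = sp$name, found = FALSE, cx = NA_real_,
                        cy = NA_real_, area = sizes[best]))
    }
    idx <- which(lab == best, arr.ind = TRUE)
    data.frame(name = sp$name, found = TRUE,
               cx = mean(idx[, 2]), cy = mean(idx[, 1]),
               area = sizes[best])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ratiometric tip and pose estimation
#'
#' The known physical marker separation fixes the per-frame image scale,
#' `mm_per_px = marker_separation_mm / |distal - proximal|`, and the tip
#' is extrapolated along the marker axis:
#' `tip = distal + (distal - proximal) * tip_offset_mm / marker_separation_mm`.
#' Equivariant under translation, rotation, and uniform scaling of the
#' marker pair (scaling rescales `mm_per_px` inversely).
#'
#' @param proximal_px,distal_px Marker centroids `(x, y)` in pixels.
#' @param geom A [probe_geometry()].
#' @return A `probe_pose` list: `proximal_px`, `distal_px`, `tip_px`,
#'   `angle_rad` (atan2 of distal - proximal), `mm_per_px`, `valid`.
#'   Coincident or missing centroids yield an invalid pose.
#' @export
estimate_tip <- function(proximal_px, distal_px, geom) {
  stopifnot(inherits(geom, "probe_geometry"))
  invalid <- structure(
    list(proximal_px = c(NA_real_, NA_real_), distal_px = c(NA_real_, NA_real_),
         tip_px = c(NA_real_, NA_real_), angle_rad = NA_real_,
         mm_per_px = NA_real_, valid = FALSE),
    class = "probe_pose")
  if (any(!is.finite(proximal_px)) || any(!is.finite(distal_px))) {
    return(invalid)
  }
  v <- distal_px - proximal_px
  sep_px <- sqrt(sum(v^2))
  if (sep_px < 1e-9) return(invalid)
  tip <- distal_px + v * (geom$tip_offset_mm / geom$marker_separation_mm)
  structure(
    list(proximal_px = as.numeric(proximal_px),
         distal_px = as.numeric(distal_px),
         tip_px = as.numeric(tip),
         angle_rad = atan2(v[2], v[1]),
         mm_per_px = geom$marker_separation_mm / sep_px,
         valid = TRUE),
    class = "probe_pose")
}

#' Track the probe through a video
#'
#' Processes every frame independently — no temporal state, no pose
#' carry-over — so the tracker recovers immediately after temporary
#' occlusion of the probe. Frames with any marker miss are flagged
#' `valid = FALSE`.
#'
#' @param frames Character vector of PNG paths (read one at a time) or a
#'   list of frame arrays.
#' @param specs Named list of [marker_spec()] objects containing
#'   `"proximal"` and `"distal"`.
#' @param geom A [probe_geometry()].
#' @return Data frame with one row per frame: `frame`, `valid`,
#'   `mx1,my1` (proximal), `mx2,my2` (distal), `tipx,tipy`, `angle`,
#'   `mm_per_px`.
#' @export
track_video <- function(frames, specs, geom) {
  if (length(frames) == 0) stop("no frames to track", call. = FALSE)
  if (!all(c("proximal", "distal") %in% names(specs))) {
    stop("specs must be a named list with 'proximal' and 'distal'",
         call. = FALSE)
  }
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (is.character(fr)) fr <- png::readPNG(fr)
    seg <- segment_markers(fr, specs[c("proximal", "distal")])
    prox <- seg[seg$name == "proximal", ]
    dist <- seg[seg$name == "distal", ]
    pose <- if (prox$found && dist$found) {
      estimate_tip(c(prox$cx, prox$cy), c(dist$cx, dist$cy), geom)
    } else {
      estimate_tip(c(NA_real_, NA_real_), c(NA_real_, NA_real_), geom)
    }
    rows[[i]] <- data.frame(
      frame = i, valid = pose$valid,
      mx1 = pose$proximal_px[1], my1 = pose$proximal_px[2],
      mx2 = pose$distal_px[1], my2 = pose$distal_px[2],
      tipx = pose$tip_px[1], tipy = pose$tip_px[2],
      angle = pose$angle_rad, mm_per_px = pose$mm_per_px)
  }
  do.call(rbind, rows)
}
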