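#' Synthetic probe-video specification
#'
#' Defines a rendered video of a handheld probe moving over a scene: two
#' colored fiducial marker disks at saturated, distinct hues on a
#' low-saturation background (guaranteeing HSV separability), a known tip
#' trajectory, and optional occlusion frames in which no markers are
#' drawn. Marker positions are placed so that the ratiometric tip formula
#' applied to the exact disk centers reproduces the ground-truth tip.
#'
#' @param n_frames Number of frames (> 0).
#' @param marker_hues Named numeric vector `c(proximal = , distal = )` of
#'   distinct hues in degrees (defaults green 120 / blue 240).
#' @param marker_radius_px Disk radius in pixels.
#' @param marker_separation_mm,tip_offset_mm Probe geometry (see
#'   [probe_geometry()]).
#' @param trajectory Data frame with columns `x`, `y` (ground-truth tip,
#'   pixels) and `angle` (probe axis orientation, radians, pointing from
#'   markers toward the tip), one row per frame. Defaults to a smooth
#'   Lissajous sweep via [default_trajectory()] at render time.
#' @param occluded_frames Integer vector of frame indices rendered without
#'   markers.
#' @param seed Integer seed (reserved for stochastic scene texture).
#' @return An object of class `video_gen_spec`.
#' @export
video_gen_spec <- function(n_frames = 180L,
                           marker_hues = c(proximal = 120, distal = 240),
                           marker_radius_px = 8,
                           marker_separation_mm = 20,
                           tip_offset_mm = 30,
                           trajectory = NULL,
                           occluded_frames = integer(0),
                           seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be positive", call. = FALSE)
  if (!all(c("proximal", "distal") %in% names(marker_hues))) {
    stop("marker_hues needs named entries 'proximal' and 'distal'", call. = FALSE)
  }
  if (hue_distance(marker_hues[["proximal"]], marker_hues[["distal"]]) < 1e-9) {
    stop("marker hues must be distinct", call. = FALSE)
  }
  if (marker_separation_mm <= 0 || tip_offset_mm < 0) {
    stop("marker_separation_mm > 0 and tip_offset_mm >= 0 required", call. = FALSE)
  }
  if (!is.null(trajectory)) {
    trajectory <- as.data.frame(trajectory)
    if (!all(c("x", "y", "angle") %in% names(trajectory))) {
      stop("trajectory needs columns x, y, angle", call. = FALSE)
    }
    if (nrow(trajectory) != n_frames) {
      stop("trajectory length must equal n_frames", call. = FALSE)
    }
  }
  structure(list(n_frames = n_frames, marker_hues = marker_hues,
                 marker_radius_px = marker_radius_px,
                 marker_separation_mm = marker_separation_mm,
                 tip_offset_mm = tip_offset_mm,
                 trajectory = trajectory,
                 occluded_frames = as.integer(occluded_frames),
                 seed = as.integer(seed)),
            class = "video_gen_spec")
}

#' Smooth default tip trajectory
#'
#' A Lissajous-like sweep of the tip over the central region of the scene
#' with slowly varying orientation, chosen so that both markers stay
#' inside the frame for the default geometry.
#'
#' @param n_frames Number of frames.
#' @param scene A [scene_spec()] fixing the frame size.
#' @return Data frame with columns `x`, `y`, `angle`.
#' @export
default_trajectory <- function(n_frames, scene) {
  t <- seq(0, 2 * pi, length.out = n_frames)
  cx <- scene$width_px / 2; cy <- scene$height_px / 2
  data.frame(
    x = cx + 0.22 * scene$width_px * sin(t),
    y = cy + 0.22 * scene$height_px * sin(2 * t + pi / 3),
    angle = pi / 4 + 0.6 * sin(t + pi / 6)
  )
}

# marker centers implied by a ground-truth tip + orientation (inverse of
# the ratiometric tip formula); angle points from the markers to the tip
marker_positions <- function(tip, angle, video, mm_per_px) {
  u <- c(cos(angle), sin(angle))
  distal <- tip - u * video$tip_offset_mm / mm_per_px
  proximal <- distal - u * video$marker_separation_mm / mm_per_px
  list(proximal = proximal, distal = distal)
}

# paint an anti-aliased filled disk onto a frame array (in place semantics)
draw_disk <- function(frame, center, radius, rgb) {
  d <- dim(frame)
  x0 <- max(1L, floor(center[1] - radius - 2))
  x1 <- min(d[2], ceiling(center[1] + radius + 2))
  y0 <- max(1L, floor(center[2] - radius - 2))
  y1 <- min(d[1], ceiling(center[2] + radius + 2))
  if (x0 > x1 || y0 > y1) return(frame)
  xs <- matrix(x0:x1, y1 - y0 + 1, x1 - x0 + 1, byrow = TRUE)
  ys <- matrix(y0:y1, y1 - y0 + 1, x1 - x0 + 1)
  dist <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  alpha <- pmin(1, pmax(0, radius - dist + 0.5))
  for (ch in 1:3) {
    patch <- frame[y0:y1, x0:x1, ch]
    frame[y0:y1, x0:x1, ch] <- alpha * rgb[ch] + (1 - alpha) * patch
  }
  frame
}

# low-saturation gray background with the lesion region slightly darker;
# saturation stays far below any calibrated marker threshold
render_scene_background <- function(scene) {
  base <- matrix(0.55, scene$height_px, scene$width_px)
  base[scene$lesion_mask] <- 0.42
  frame <- array(0, c(scene$height_px, scene$width_px, 3))
  frame[, , 1] <- base
  frame[, , 2] <- base
  frame[, , 3] <- base * 0.97 + 0.01
  frame
}

#' Render one probe-video frame
#'
#' @param scene A [scene_spec()].
#' @param video A [video_gen_spec()].
#' @param i Frame index (1-based).
#' @param trajectory Resolved trajectory data frame (defaults to the
#'   video's, or [default_trajectory()]).
#' @return Frame array `height x width x 3` in `[0, 1]`.
#' @export
render_probe_frame <- function(scene, video, i, trajectory = NULL) {
  if (is.null(trajectory)) {
    trajectory <- if (is.null(video$trajectory)) {
      default_trajectory(video$n_frames, scene)
    } else video$trajectory
  }
  frame <- render_scene_background(scene)
  if (i %in% video$occluded_frames) return(frame)
  pos <- marker_positions(c(trajectory$x[i], trajectory$y[i]),
                          trajectory$angle[i], video, scene$mm_per_px)
  cols <- lapply(video$marker_hues, function(h) {
    as.numeric(grDevices::col2rgb(grDevices::hsv(h / 360, 1, 1))) / 255
  })
  frame <- draw_disk(frame, pos$proximal, video$marker_radius_px,
                     cols$proximal)
  draw_disk(frame, pos$distal, video$marker_radius_px, cols$distal)
}

#' Generate a probe-motion video with ground truth
#'
#' Renders every frame (see [render_probe_frame()]) and tabulates the
#' exact marker centers and tip coordinates. With `dir` set, frames are
#' written as a zero-padded PNG sequence (`frame_0001.png`, ...) and the
#' return value references the files — the memory-friendly mode for long
#' videos; otherwise the frames are returned as arrays.
#'
#' @param scene A [scene_spec()].
#' @param video A [video_gen_spec()].
#' @param dir Optional output directory for the PNG sequence.
#' @return List with `frames` (paths or arrays) and `truth`, a data frame
#'   `frame, occluded, mx1, my1, mx2, my2, tipx, tipy, angle` of exact
#'   ground truth (marker columns are the true disk centers also for
#'   occluded frames, where nothing is rendered).
#' @export
generate_probe_video <- function(scene, video, dir = NULL) {
  stopifnot(inherits(scene, "scene_spec"), inherits(video, "video_gen_spec"))
  trajectory <- if (is.null(video$trajectory)) {
    default_trajectory(video$n_frames, scene)
  } else video$trajectory
  truth <- vector("list", video$n_frames)
  frames <- if (is.null(dir)) vector("list", video$n_frames) else
    character(video$n_frames)
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  for (i in seq_len(video$n_frames)) {
    fr <- render_probe_frame(scene, video, i, trajectory)
    if (is.null(dir)) {
      frames[[i]] <- fr
    } else {
      frames[i] <- file.path(dir, sprintf("frame_%04d.png", i))
      png::writePNG(fr, frames[i])
    }
    pos <- marker_positions(c(trajectory$x[i], trajectory$y[i]),
                            trajectory$angle[i], video, scene$mm_per_px)
    truth[[i]] <- data.frame(
      frame = i, occluded = i %in% video$occluded_frames,
      mx1 = pos$proximal[1], my1 = pos$proximal[2],
      mx2 = pos$distal[1], my2 = pos$distal[2],
      tipx = trajectory$x[i], tipy = trajectory$y[i],
      angle = trajectory$angle[i])
  }
  list(frames = frames, truth = do.call(rbind, truth))
}
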