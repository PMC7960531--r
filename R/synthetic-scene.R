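#' Synthetic 2D scene specification
#'
#' A bench-top scene with a known ground-truth lesion: image size, binary
#' lesion mask, mm-per-pixel scale, and two optional co-registered maps —
#' a fluorophore (PPIX-analog) concentration map (µM-like units) and an
#' occluding-layer thickness map (mm) that attenuates fluorescence, as in
#' a composite phantom whose low-concentration region sits under a thin
#' layer of non-fluorescent material.
#'
#' @param width_px,height_px Image size in pixels.
#' @param lesion_mask Logical/0-1 matrix `height_px x width_px`; the
#'   ground-truth diseased region.
#' @param mm_per_px Positive scalar scale.
#' @param concentration_map Numeric matrix, same shape, values >= 0
#'   (default all zero).
#' @param occlusion_map Numeric matrix of layer thickness in mm, same
#'   shape, values >= 0 (default all zero).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_px, height_px, lesion_mask = NULL,
                       mm_per_px = 0.5, concentration_map = NULL,
                       occlusion_map = NULL) {
  if (mm_per_px <= 0) stop("mm_per_px must be positive", call. = FALSE)
  shape <- c(height_px, width_px)
  if (is.null(lesion_mask)) lesion_mask <- matrix(FALSE, shape[1], shape[2])
  if (is.null(concentration_map)) concentration_map <- matrix(0, shape[1], shape[2])
  if (is.null(occlusion_map)) occlusion_map <- matrix(0, shape[1], shape[2])
  for (m in list(lesion_mask, concentration_map, occlusion_map)) {
    if (!is.matrix(m) || !all(dim(m) == shape)) {
      stop("masks and maps must share the scene shape (height x width)",
           call. = FALSE)
    }
  }
  storage.mode(lesion_mask) <- "logical"
  if (any(concentration_map < 0) || any(occlusion_map < 0)) {
    stop("concentrations and occlusion thicknesses must be >= 0", call. = FALSE)
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 lesion_mask = lesion_mask, mm_per_px = mm_per_px,
                 concentration_map = concentration_map,
                 occlusion_map = occlusion_map),
            class = "scene_spec")
}

#' Elliptical lesion scene
#'
#' Convenience constructor: a centered elliptical lesion (the ground-truth
#' region) with uniform fluorophore concentration inside it.
#'
#' @inheritParams scene_spec
#' @param center `(x, y)` lesion center in pixels (default scene center).
#' @param semi_axes `(a, b)` ellipse semi-axes in pixels.
#' @param concentration Uniform concentration inside the lesion.
#' @return A [scene_spec()].
#' @export
elliptical_lesion_scene <- function(width_px = 640, height_px = 480,
                                    center = c(width_px / 2, height_px / 2),
                                    semi_axes = c(width_px / 6, height_px / 6),
                                    mm_per_px = 0.5, concentration = 0) {
  xs <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
  ys <- matrix(seq_len(height_px), height_px, width_px)
  inside <- ((xs - center[1]) / semi_axes[1])^2 +
    ((ys - center[2]) / semi_axes[2])^2 <= 1
  scene_spec(width_px, height_px, lesion_mask = inside, mm_per_px = mm_per_px,
             concentration_map = inside * concentration)
}

#' Simulated fluorescence image of a scene
#'
#' Wide-field fluorescence intensity under the scene's concentration and
#' occlusion maps:
#' `I(x, y) = gain * C(x, y) * exp(-attenuation_per_mm * d(x, y)) + noise`,
#' where `d` is the occluding-layer thickness. Zero concentration yields a
#' noise-only background, so a non-fluorescent phantom is invisible to
#' thresholding regardless of its Raman contrast.
#'
#' @param scene A [scene_spec()].
#' @param gain Detector gain (> 0), intensity units per concentration unit.
#' @param noise_sd Additive Gaussian noise SD (>= 0).
#' @param attenuation_per_mm Exponential attenuation coefficient of the
#'   occluding layer (>= 0, per mm).
#' @param seed Integer seed for the noise draw.
#' @return Numeric matrix `height_px x width_px`.
#' @export
generate_fluorescence_image <- function(scene, gain = 1, noise_sd = 0,
                                        attenuation_per_mm = 0, seed = 1L) {
  stopifnot(inherits(scene, "scene_spec"))
  if (gain <= 0) stop("gain must be positive", call. = FALSE)
  if (attenuation_per_mm < 0 || noise_sd < 0) {
    stop("attenuation_per_mm and noise_sd must be >= 0", call. = FALSE)
  }
  img <- gain * scene$concentration_map *
    exp(-attenuation_per_mm * scene$occlusion_map)
  if (noise_sd > 0) {
    img <- img + withr::with_seed(
      as.integer(seed),
      matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img), ncol(img)))
  }
  img
}
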