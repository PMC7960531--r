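#' Preprocessing configuration
#'
#' Parameters of the fixed preprocessing chain applied to every spectrum
#' before modelling: crop to the fingerprint region, Whittaker background
#' subtraction, normalization, Savitzky-Golay filtering.
#'
#' @param crop_low,crop_high Fingerprint-region crop window (cm^-1).
#' @param whittaker_lambda Smoothness penalty of the Whittaker background
#'   estimator (larger = smoother baseline).
#' @param whittaker_p Asymmetry weight in (0, 1): points above the current
#'   baseline get weight `p`, points below get `1 - p`, pushing the
#'   baseline toward the lower envelope.
#' @param whittaker_iters Number of weight re-estimation rounds.
#' @param whittaker_diff_order Order of the finite-difference penalty.
#' @param norm_mode One of `"area"` (trapezoidal area under the curve = 1,
#'   the default everywhere), `"max"` or `"vector"`.
#' @param sg_order,sg_frame Savitzky-Golay polynomial order and odd window
#'   length.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(crop_low = 600, crop_high = 1800,
                              whittaker_lambda = 1e5,
                              whittaker_p = 0.01,
                              whittaker_iters = 10L,
                              whittaker_diff_order = 2L,
                              norm_mode = c("area", "max", "vector"),
                              sg_order = 1L, sg_frame = 7L) {
  norm_mode <- match.arg(norm_mode)
  if (crop_low >= crop_high) stop("crop_low must be < crop_high", call. = FALSE)
  if (whittaker_lambda <= 0) stop("whittaker_lambda must be > 0", call. = FALSE)
  if (whittaker_p <= 0 || whittaker_p >= 1) {
    stop("whittaker_p must lie in (0, 1)", call. = FALSE)
  }
  if (sg_frame %% 2 == 0 || sg_frame <= sg_order) {
    stop("sg_frame must be odd and greater than sg_order", call. = FALSE)
  }
  structure(
    list(crop_low = crop_low, crop_high = crop_high,
         whittaker_lambda = whittaker_lambda, whittaker_p = whittaker_p,
         whittaker_iters = as.integer(whittaker_iters),
         whittaker_diff_order = as.integer(whittaker_diff_order),
         norm_mode = norm_mode,
         sg_order = as.integer(sg_order), sg_frame = as.integer(sg_frame)),
    class = "preprocess_config"
  )
}

#' Crop a spectrum to a wavenumber window
#'
#' @param s A [raman_spectrum()].
#' @param low,high Inclusive window bounds (cm^-1); defaults are the
#'   600-1800 cm^-1 fingerprint region.
#' @return A [raman_spectrum()] containing exactly the points with
#'   `low <= wavenumber <= high`, order preserved.
#' @export
crop_spectrum <- function(s, low = 600, high = 1800) {
  stopifnot(inherits(s, "raman_spectrum"))
  keep <- s$wavenumbers >= low & s$wavenumbers <= high
  if (sum(keep) < 2L) {
    stop(sprintf("crop window [%g, %g] does not overlap the axis [%g, %g]",
                 low, high, min(s$wavenumbers), max(s$wavenumbers)),
         call. = FALSE)
  }
  raman_spectrum(s$wavenumbers[keep], s$intensities[keep], s$meta)
}

#' Whittaker background estimation (asymmetric penalized least squares)
#'
#' Estimates a smooth baseline `z` minimizing
#' `sum(w_i (y_i - z_i)^2) + lambda * sum((diff(z, d))^2)`
#' with asymmetric weights re-estimated for `iters` rounds
#' (`w = p` where `y > z`, `1 - p` otherwise), so the baseline hugs the
#' lower envelope of the spectrum — the usual way a Whittaker filter is
#' deployed for fluorescence background subtraction. Solved with a sparse
#' banded system, O(n) in spectrum length.
#'
#' @param y Intensity vector.
#' @inheritParams preprocess_config
#' @param lambda,p,iters,diff_order See [preprocess_config()].
#' @return Baseline vector of the same length as `y`.
#' @export
whittaker_background <- function(y, lambda = 1e5, p = 0.01, iters = 10L,
                                 diff_order = 2L) {
  n <- length(y)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (n < diff_order + 2L) {
    stop("spectrum too short for the requested difference order", call. = FALSE)
  }
  D <- Matrix::Diagonal(n)
  for (d in seq_len(diff_order)) {
    D <- D[-1, , drop = FALSE] - D[-nrow(D), , drop = FALSE]
  }
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iters)) {
    W <- Matrix::Diagonal(n, x = w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Subtract the Whittaker background from a spectrum
#'
#' @param s A [raman_spectrum()].
#' @param config A [preprocess_config()].
#' @return A [raman_spectrum()] with `intensities - baseline`; axis
#'   unchanged.
#' @export
subtract_background <- function(s, config = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"))
  z <- whittaker_background(s$intensities,
                            lambda = config$whittaker_lambda,
                            p = config$whittaker_p,
                            iters = config$whittaker_iters,
                            diff_order = config$whittaker_diff_order)
  raman_spectrum(s$wavenumbers, s$intensities - z, s$meta)
}

#' Normalize a spectrum
#'
#' @param s A [raman_spectrum()].
#' @param mode `"area"` divides by the trapezoidal integral of the
#'   intensities over the wavenumber axis (area under the curve = 1),
#'   `"max"` by the maximum, `"vector"` by the Euclidean norm. All modes
#'   are invariant to positive scaling of the input.
#' @return Normalized [raman_spectrum()].
#' @export
normalize_spectrum <- function(s, mode = c("area", "max", "vector")) {
  stopifnot(inherits(s, "raman_spectrum"))
  mode <- match.arg(mode)
  y <- s$intensities
  nrm <- switch(mode,
    area = sum(diff(s$wavenumbers) * (utils::head(y, -1) + utils::tail(y, -1)) / 2),
    max = max(y),
    vector = sqrt(sum(y^2))
  )
  if (!is.finite(nrm) || nrm <= 0) {
    stop(sprintf("cannot normalize: %s norm is %g", mode, nrm), call. = FALSE)
  }
  raman_spectrum(s$wavenumbers, y / nrm, s$meta)
}

#' Savitzky-Golay filtering with mirror padding
#'
#' Replaces each point by the center value of a local least-squares
#' polynomial fit of the given order over an odd window. Edges are handled
#' by mirror padding (reflection about the first/last sample), which
#' preserves length and avoids transients at the crop boundaries. The
#' central convolution coefficients come from [signal::sgolay()].
#'
#' @param y Numeric vector, `length(y) >= frame`.
#' @param order Polynomial order (default 1).
#' @param frame Odd window length (default 7), `frame > order`.
#' @return Smoothed vector of the same length.
#' @export
savitzky_golay <- function(y, order = 1L, frame = 7L) {
  if (frame %% 2 == 0) stop("frame must be odd", call. = FALSE)
  if (frame <= order) stop("frame must exceed the polynomial order", call. = FALSE)
  n <- length(y)
  if (n < frame) stop("input shorter than the filter frame", call. = FALSE)
  k <- (frame - 1L) / 2L
  coefs <- signal::sgolay(p = order, n = frame)[k + 1L, ]
  padded <- c(y[(k + 1L):2L], y, y[(n - 1L):(n - k)])
  out <- stats::filter(padded, coefs, sides = 2)
  as.numeric(out[(k + 1L):(n + k)])
}

#' Full preprocessing chain
#'
#' Applies, in order: crop to the fingerprint window, Whittaker background
#' subtraction, normalization, Savitzky-Golay filtering. The chain is
#' deterministic and invariant to positive scaling of the raw intensities
#' (scale cancels in the normalization step).
#'
#' @param s A [raman_spectrum()].
#' @param config A [preprocess_config()].
#' @return The preprocessed [raman_spectrum()].
#' @export
preprocess <- function(s, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  s <- crop_spectrum(s, config$crop_low, config$crop_high)
  s <- subtract_background(s, config)
  s <- normalize_spectrum(s, config$norm_mode)
  raman_spectrum(s$wavenumbers,
                 savitzky_golay(s$intensities, config$sg_order, config$sg_frame),
                 s$meta)
}

#' Preprocess a set of spectra into a modelling matrix
#'
#' Convenience wrapper running [preprocess()] over a list of spectra that
#' share an acquisition axis and stacking the results row-wise.
#'
#' @param spectra List of [raman_spectrum()] objects on a common axis.
#' @param labels Character vector of class labels, one per spectrum.
#' @param config A [preprocess_config()].
#' @return A [spectral_dataset()].
#' @export
preprocess_set <- function(spectra, labels, config = preprocess_config()) {
  stopifnot(length(spectra) == length(labels), length(spectra) >= 1)
  pp <- lapply(spectra, preprocess, config = config)
  axis <- pp[[1]]$wavenumbers
  for (s in pp) {
    if (length(s$wavenumbers) != length(axis) ||
        any(abs(s$wavenumbers - axis) > 1e-9)) {
      stop("all spectra must share one wavenumber axis after cropping",
           call. = FALSE)
    }
  }
  m <- do.call(rbind, lapply(pp, `[[`, "intensities"))
  spectral_dataset(m, labels, axis)
}
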