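#' Specification for a synthetic Raman spectrum class
#'
#' Describes one spectral class as a sum of Gaussian peaks on a smooth
#' polynomial baseline, an optional broad fluorescence background whose
#' amplitude plays the role of a fluorophore (PPIX-analog) concentration,
#' and additive Gaussian noise. Distinct classes use distinct peak sets so
#' that class separability is controlled entirely by the spec.
#'
#' @param class_name Text label for the class.
#' @param peak_centers,peak_heights,peak_widths Equal-length numeric vectors:
#'   Gaussian peak positions (cm^-1), heights (>= 0) and standard deviations
#'   (cm^-1, > 0).
#' @param baseline_coeffs Polynomial coefficients (intercept first) evaluated
#'   on `wavenumber / 1000` to keep magnitudes comparable across the axis.
#' @param fluor_amplitude Non-negative scalar scaling the broad fluorescence
#'   background template (concentration analog, in arbitrary µM-like units).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param axis_start,axis_end,axis_step Wavenumber axis definition (cm^-1).
#'   The default 400-2000 cm^-1 axis comfortably covers the 600-1800 cm^-1
#'   fingerprint region the pipeline crops to.
#' @return An object of class `spectrum_gen_spec`.
#' @export
spectrum_gen_spec <- function(class_name,
                              peak_centers = numeric(0),
                              peak_heights = numeric(0),
                              peak_widths = numeric(0),
                              baseline_coeffs = 0,
                              fluor_amplitude = 0,
                              noise_sd = 0,
                              axis_start = 400,
                              axis_end = 2000,
                              axis_step = 2) {
  n <- length(peak_centers)
  if (length(peak_heights) != n || length(peak_widths) != n) {
    stop("peak_centers, peak_heights and peak_widths must have equal length",
         call. = FALSE)
  }
  if (n > 0 && (any(peak_heights < 0) || any(peak_widths <= 0))) {
    stop("peak heights must be >= 0 and widths > 0", call. = FALSE)
  }
  if (axis_start >= axis_end || axis_step <= 0) {
    stop("need axis_start < axis_end and axis_step > 0", call. = FALSE)
  }
  if (fluor_amplitude < 0 || noise_sd < 0) {
    stop("fluor_amplitude and noise_sd must be non-negative", call. = FALSE)
  }
  structure(
    list(class_name = as.character(class_name),
         peak_centers = as.numeric(peak_centers),
         peak_heights = as.numeric(peak_heights),
         peak_widths = as.numeric(peak_widths),
         baseline_coeffs = as.numeric(baseline_coeffs),
         fluor_amplitude = as.numeric(fluor_amplitude),
         noise_sd = as.numeric(noise_sd),
         axis_start = axis_start, axis_end = axis_end, axis_step = axis_step),
    class = "spectrum_gen_spec"
  )
}

#' Broad fluorescence background template
#'
#' A single broad Gaussian centered mid-axis with a 400 cm^-1 standard
#' deviation: a deliberately generic stand-in for the slowly varying
#' fluorescence background that high fluorophore concentrations superimpose
#' on tissue Raman spectra. Unit amplitude; scaled by `fluor_amplitude`.
#'
#' @param wavenumbers Axis on which to evaluate the template.
#' @param axis_start,axis_end Axis limits defining the template center.
#' @return Numeric vector in `[0, 1]`, same length as `wavenumbers`.
#' @export
fluorescence_template <- function(wavenumbers,
                                  axis_start = min(wavenumbers),
                                  axis_end = max(wavenumbers)) {
  center <- (axis_start + axis_end) / 2
  exp(-0.5 * ((wavenumbers - center) / 400)^2)
}

#' Generate one synthetic Raman spectrum
#'
#' Intensities are the sum of the spec's Gaussian peaks, the polynomial
#' baseline, `fluor_amplitude` times the broad [fluorescence_template()],
#' and i.i.d. Gaussian noise. A pure function of `(spec, seed)`.
#'
#' @param spec A [spectrum_gen_spec()].
#' @param seed Integer seed controlling the noise draw.
#' @return A [raman_spectrum()] with `meta$class` set from the spec.
#' @export
generate_spectrum <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "spectrum_gen_spec"))
  w <- seq(spec$axis_start, spec$axis_end, by = spec$axis_step)
  y <- rep(0, length(w))
  for (i in seq_along(spec$peak_centers)) {
    y <- y + spec$peak_heights[i] *
      exp(-0.5 * ((w - spec$peak_centers[i]) / spec$peak_widths[i])^2)
  }
  # baseline evaluated on w/1000 so coefficient magnitudes stay tame
  wb <- w / 1000
  for (k in seq_along(spec$baseline_coeffs)) {
    y <- y + spec$baseline_coeffs[k] * wb^(k - 1)
  }
  y <- y + spec$fluor_amplitude *
    fluorescence_template(w, spec$axis_start, spec$axis_end)
  if (spec$noise_sd > 0) {
    y <- y + withr::with_seed(as.integer(seed),
                              stats::rnorm(length(w), 0, spec$noise_sd))
  }
  raman_spectrum(w, y, meta = list(class = spec$class_name, seed = seed))
}

#' Generate a labelled set of synthetic spectra
#'
#' Draws `n_per_class` spectra from each spec with seeds fanned out
#' deterministically from `seed`, mimicking repeated acquisitions from a
#' set of tissue or phantom classes.
#'
#' @param specs List of [spectrum_gen_spec()] objects (distinct class names).
#' @param n_per_class Number of spectra per class (recycled across specs).
#' @param seed Base integer seed.
#' @return List with `spectra` (list of [raman_spectrum()]) and `labels`
#'   (character vector, one per spectrum, in generation order).
#' @export
generate_spectra_set <- function(specs, n_per_class = 25L, seed = 1L) {
  stopifnot(length(specs) >= 1, all(vapply(specs, inherits, TRUE,
                                           "spectrum_gen_spec")))
  n_per_class <- rep_len(as.integer(n_per_class), length(specs))
  spectra <- list()
  labels <- character(0)
  k <- 0L
  for (j in seq_along(specs)) {
    for (i in seq_len(n_per_class[j])) {
      k <- k + 1L
      spectra[[k]] <- generate_spectrum(specs[[j]], seed = seed + 1000L * k)
      labels[k] <- specs[[j]]$class_name
    }
  }
  list(spectra = spectra, labels = labels)
}

#' Default synthetic class specifications
#'
#' The two-class bench model used throughout: a muscle-tissue analog with
#' protein/amide-like bands (1003, 1265, 1445, 1655 cm^-1 and 855 cm^-1)
#' and a non-fluorescent polymer phantom analog with a disjoint peak set.
#' `fluor_amplitude` adds the concentration-dependent fluorescence
#' background of PPIX-doped phantoms (0/2/4/20 analog units).
#'
#' @param noise_sd Acquisition noise (default 0.3 against peak heights ~10).
#' @param fluor_amplitude Fluorescence background amplitude for the phantom
#'   class (0 = non-fluorescent phantom).
#' @return Named list with elements `muscle` and `phantom`.
#' @export
default_class_specs <- function(noise_sd = 0.3, fluor_amplitude = 0) {
  list(
    muscle = spectrum_gen_spec(
      "muscle",
      peak_centers = c(855, 1003, 1265, 1445, 1655),
      peak_heights = c(6, 10, 5, 8, 9),
      peak_widths  = c(12, 8, 15, 14, 16),
      baseline_coeffs = c(2, 1, 0.5),
      noise_sd = noise_sd
    ),
    phantom = spectrum_gen_spec(
      "phantom",
      peak_centers = c(700, 950, 1100, 1350, 1600),
      peak_heights = c(8, 7, 10, 6, 7),
      peak_widths  = c(10, 12, 9, 14, 11),
      baseline_coeffs = c(3, 0.5, 0.2),
      fluor_amplitude = fluor_amplitude,
      noise_sd = noise_sd
    )
  )
}
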