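#' Construct a Raman spectrum
#'
#' The basic acquisition unit: a strictly increasing wavenumber axis
#' (Raman shift, cm^-1) with one intensity value per axis point, plus a
#' free-form metadata list (class label, acquisition index, ...).
#'
#' @param wavenumbers Numeric vector of Raman shifts (cm^-1), strictly
#'   increasing, length >= 2.
#' @param intensities Numeric vector of the same length (arbitrary counts).
#' @param meta Named list of metadata carried through processing.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) < 2L) {
    stop("a raman_spectrum needs at least 2 axis points", call. = FALSE)
  }
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  }
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0)) {
    stop("wavenumber axis must be finite and strictly increasing", call. = FALSE)
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         meta = as.list(meta)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum> %d points, %.1f-%.1f cm^-1%s\n",
    length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
    if (!is.null(x$meta$class)) paste0(", class: ", x$meta$class) else ""
  ))
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

#' Read / write a spectrum as CSV
#'
#' Plain two-column CSV with header `wavenumber,intensity`, the on-disk
#' interchange format used throughout the package.
#'
#' @param path File path.
#' @param meta Metadata attached to the spectrum on read.
#' @return `read_spectrum_csv` returns a [raman_spectrum()];
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, meta = list()) {
  d <- utils::read.csv(path)
  if (!all(c("wavenumber", "intensity") %in% names(d))) {
    stop("spectrum CSV must have columns wavenumber,intensity", call. = FALSE)
  }
  raman_spectrum(d$wavenumber, d$intensity, meta)
}

#' @param s A [raman_spectrum()].
#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "raman_spectrum"))
  utils::write.csv(
    data.frame(wavenumber = s$wavenumbers, intensity = s$intensities),
    path, row.names = FALSE
  )
  invisible(path)
}
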