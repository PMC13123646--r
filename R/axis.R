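#' Spectral axis of a hyperspectral cube
#'
#' A spectral axis is the ordered vector of band-center wavelengths of a
#' cube.  The default axis mirrors the push-broom SWIR system the package
#' targets: 512 bands linearly spaced over 900--1700 nm.
#'
#' @param wavelengths_nm Numeric vector of strictly increasing band-center
#'   wavelengths in nanometres.  Defaults to 512 bands over 900--1700 nm.
#' @return An object of class `spectral_axis` with fields `wavelengths_nm`
#'   and `L` (band count).
#' @examples
#' ax <- spectral_axis()
#' ax$L
#' @export
spectral_axis <- function(wavelengths_nm = seq(900, 1700, length.out = 512)) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) < 1L || anyNA(wavelengths_nm)) {
    stop("spectral axis needs at least one finite wavelength")
  }
  if (is.unsorted(wavelengths_nm, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  structure(list(wavelengths_nm = wavelengths_nm, L = length(wavelengths_nm)),
            class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d bands, %.1f-%.1f nm\n",
              x$L, min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Band index nearest to a wavelength
#'
#' Returns the 1-based index of the band whose center is closest to
#' `wavelength_nm`; ties break toward the lower index.
#'
#' @param axis A [spectral_axis()].
#' @param wavelength_nm Query wavelength in nm; must lie within the axis
#'   range.
#' @return Integer band index.
#' @export
nearest_band <- function(axis, wavelength_nm) {
  stopifnot(inherits(axis, "spectral_axis"), length(wavelength_nm) == 1L)
  w <- axis$wavelengths_nm
  if (wavelength_nm < w[1L] || wavelength_nm > w[axis$L]) {
    stop(sprintf("wavelength %.1f nm outside axis range [%.1f, %.1f]",
                 wavelength_nm, w[1L], w[axis$L]))
  }
  # which.min returns the first (lowest-index) minimizer, the required
  # tie-break
  which.min(abs(w - wavelength_nm))
}

axes_identical <- function(a, b, tol = 1e-9) {
  a$L == b$L && max(abs(a$wavelengths_nm - b$wavelengths_nm)) <= tol
}
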