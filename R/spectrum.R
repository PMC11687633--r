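#' Wavelength-indexed spectrum
#'
#' The universal currency of the package: an intensity trace on a strictly
#' increasing wavelength grid, tagged as diffuse reflectance or fluorescence.
#' `meta` carries free-form provenance (channel, fluorophore, time stamp,
#' calibration flag) that survives file round trips.
#'
#' @param wavelength_nm numeric, strictly increasing wavelengths (nm).
#' @param value numeric intensities, same length, finite and non-negative.
#' @param kind `"reflectance"` or `"fluorescence"`.
#' @param meta named list of provenance entries (scalars).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("reflectance", "fluorescence"),
                     meta = list()) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value))
    stop_validation("wavelength and value lengths differ (%d vs %d)",
                    length(wavelength_nm), length(value))
  if (length(wavelength_nm) < 2L)
    stop_validation("a spectrum needs at least 2 samples")
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0))
    stop_validation("wavelength grid must be finite and strictly increasing")
  if (any(!is.finite(value)))
    stop_validation("spectrum values must be finite")
  if (any(value < 0))
    stop_validation("spectrum values must be non-negative")
  structure(list(wavelength_nm = wavelength_nm, value = value,
                 kind = kind, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.1f-%.1f nm>\n", x$kind,
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Look up a spectrum value at a wavelength
#'
#' Nearest-node lookup with a 0.5 nm tolerance; all per-wavelength reads in
#' the package (ratio wavelengths, excitation/emission peaks) go through this.
#'
#' @param s a [spectrum].
#' @param wl wavelength (nm), scalar or vector.
#' @param tol_nm maximum |grid node - wl| accepted.
#' @return numeric value(s) at the nearest grid node(s).
#' @export
spectrum_value_at <- function(s, wl, tol_nm = 0.5) {
  stopifnot(is_spectrum(s))
  vapply(wl, function(w) {
    i <- which.min(abs(s$wavelength_nm - w))
    if (abs(s$wavelength_nm[i] - w) > tol_nm)
      stop_range("wavelength %.1f nm not on grid (nearest node %.1f nm)",
                 w, s$wavelength_nm[i])
    s$value[i]
  }, numeric(1))
}

# Restrict a spectrum to [lo, hi] nm (inclusive), erroring if empty.
spectrum_window <- function(s, lo, hi) {
  keep <- s$wavelength_nm >= lo & s$wavelength_nm <= hi
  if (!any(keep))
    stop_range("no samples in the %.0f-%.0f nm window", lo, hi)
  spectrum(s$wavelength_nm[keep], s$value[keep], s$kind, s$meta)
}

assert_covers <- function(s, lo, hi, what = "spectrum") {
  if (min(s$wavelength_nm) > lo || max(s$wavelength_nm) < hi)
    stop_range("%s grid (%.1f-%.1f nm) does not cover %.0f-%.0f nm",
               what, min(s$wavelength_nm), max(s$wavelength_nm), lo, hi)
  invisible(TRUE)
}
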