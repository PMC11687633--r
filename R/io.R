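# Readers/writers for the plain-text spectra dialect, calibration against
# reflectance/fluorescence standards, and the run configuration.

#' Write / read a spectrum file
#'
#' Two delimited numeric columns (`wavelength_nm`, `value`) preceded by
#' `# key: value` metadata header lines (`kind` plus any scalar `meta`
#' entries). Round trips preserve wavelengths, values (full printed
#' precision) and metadata.
#'
#' @param s a [spectrum].
#' @param path file path.
#' @return `read_spectrum` returns a [spectrum]; `write_spectrum` returns
#'   `path` invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", s$kind), con)
  for (k in names(s$meta))
    writeLines(sprintf("# %s: %s", k, format(s$meta[[k]], digits = 17)), con)
  writeLines("wavelength_nm\tvalue", con)
  writeLines(paste(format(s$wavelength_nm, digits = 17, trim = TRUE),
                   format(s$value, digits = 17, trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop_validation("spectrum file not found: %s", path)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  body <- which(!is_meta & nzchar(trimws(lines)))
  if (length(body) < 3) stop_parse("spectrum file has no data rows: %s", path)
  header <- body[1]
  rows <- body[-1]
  parts <- strsplit(trimws(lines[rows]), "[\t ,]+")
  vals <- lapply(seq_along(parts), function(j) {
    p <- suppressWarnings(as.numeric(parts[[j]]))
    if (length(p) < 2 || any(is.na(p[1:2])))
      stop_parse("malformed numeric row at line %d of %s", rows[j], path)
    p[1:2]
  })
  mat <- do.call(rbind, vals)
  kind <- meta$kind
  meta$kind <- NULL
  if (is.null(kind)) stop_parse("spectrum file lacks a '# kind:' header: %s", path)
  spectrum(mat[, 1], mat[, 2], kind, meta)
}

#' Calibration standards
#'
#' The reflectance standard (nominal reflectivity 0.20) and fluorescence
#' standard spectra used to convert raw instrument counts to calibrated
#' units.
#'
#' @param reflectance_standard raw [spectrum] measured on the 20%
#'   reflectance standard.
#' @param fluorescence_standard raw [spectrum] measured on the fluorescence
#'   standard.
#' @param nominal_reflectivity the standard's nominal reflectivity.
#' @return An object of class `calibration_standards`.
#' @export
calibration_standards <- function(reflectance_standard,
                                  fluorescence_standard = NULL,
                                  nominal_reflectivity = 0.20) {
  stopifnot(is_spectrum(reflectance_standard))
  if (any(reflectance_standard$value <= 0))
    stop_validation("reflectance standard must be strictly positive")
  if (!is.null(fluorescence_standard)) {
    stopifnot(is_spectrum(fluorescence_standard))
    if (any(fluorescence_standard$value <= 0))
      stop_validation("fluorescence standard must be strictly positive")
  }
  structure(list(reflectance_standard = reflectance_standard,
                 fluorescence_standard = fluorescence_standard,
                 nominal_reflectivity = nominal_reflectivity),
            class = "calibration_standards")
}

#' Calibrate a raw spectrum against its standard
#'
#' Reflectance: value -> raw / standard x nominal reflectivity (0.20).
#' Fluorescence: value -> raw / standard (relative units). Any wavelength-
#' dependent instrument gain present in both raw and standard cancels
#' exactly. A `calibrated` metadata flag guards against double calibration
#' (a second call errors).
#'
#' @param raw a raw [spectrum].
#' @param standards a [calibration_standards].
#' @return The calibrated [spectrum].
#' @export
calibrate <- function(raw, standards) {
  stopifnot(is_spectrum(raw), inherits(standards, "calibration_standards"))
  if (isTRUE(raw$meta$calibrated) || identical(raw$meta$calibrated, "TRUE"))
    stop_validation("spectrum is already calibrated")
  std <- if (raw$kind == "reflectance") standards$reflectance_standard
         else standards$fluorescence_standard
  if (is.null(std)) stop_validation("no %s standard supplied", raw$kind)
  if (min(std$wavelength_nm) > min(raw$wavelength_nm) ||
      max(std$wavelength_nm) < max(raw$wavelength_nm))
    stop_range("standard does not cover the raw spectrum's grid")
  sv <- stats::approx(std$wavelength_nm, std$value, raw$wavelength_nm)$y
  if (any(sv <= 0)) stop_domain("standard is zero on the working band")
  value <- raw$value / sv
  if (raw$kind == "reflectance") value <- value * standards$nominal_reflectivity
  meta <- raw$meta
  meta$calibrated <- TRUE
  spectrum(raw$wavelength_nm, value, raw$kind, meta)
}

#' Run configuration
#'
#' A single YAML key-value file validated on load; unknown keys are
#' rejected. `default_run_config()` returns the study defaults.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    wavelength_min_nm = 400, wavelength_max_nm = 650,
    channel1_sds_mm = 1.5, channel2_sds_mm = 3.0,
    nbdg_emission_peak_nm = 545, tmre_emission_peak_nm = 580,
    noise_sd_frac = 0.01, seed = 1L,
    powers_file = NA_character_, thb_calibration_file = NA_character_,
    log_level = "info"), class = "run_config")
}

#' @param path YAML file path for `read_run_config`.
#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown))
    stop_validation("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  if (cfg$wavelength_min_nm >= cfg$wavelength_max_nm)
    stop_validation("wavelength_min_nm must be < wavelength_max_nm")
  cfg
}
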