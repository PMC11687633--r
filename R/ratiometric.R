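# Analytic vascular estimators: corrected absorbance with scattering-baseline
# removal, the two-wavelength (555/575 nm) hemoglobin solve for StO2, and the
# 584/545 nm reflectance ratio with phantom calibration for [THB].

#' Corrected absorbance of a reflectance spectrum
#'
#' A(lambda) = log10(1/R) - (a + m lambda), where (a, m) is the ordinary
#' least-squares line of log10(1/R) vs wavelength fitted over the
#' hemoglobin-free scattering band (620-680 nm). The subtraction removes the
#' smooth scattering baseline (and any multiplicative gain on R), leaving an
#' approximation to the pure absorber contribution. log10 matches the
#' base-10 extinction convention used throughout.
#'
#' @param r a reflectance [spectrum], positive, covering 555-680 nm.
#' @param fit_band baseline window `c(lo, hi)` nm.
#' @return An object of class `corrected_absorbance`: `wavelength_nm`,
#'   `a_corr`, `baseline_intercept`, `baseline_slope`, `fit_band`.
#' @export
corrected_absorbance <- function(r, fit_band = c(620, 680)) {
  stopifnot(is_spectrum(r))
  if (r$kind != "reflectance")
    stop_validation("corrected_absorbance needs a reflectance spectrum")
  assert_covers(r, 555, 680, "reflectance")
  if (any(r$value <= 0))
    stop_domain("reflectance must be strictly positive for log(1/R)")
  loginv <- log10(1 / r$value)
  inband <- r$wavelength_nm >= fit_band[1] & r$wavelength_nm <= fit_band[2]
  if (sum(inband) < 2)
    stop_range("baseline band %.0f-%.0f nm has < 2 samples",
               fit_band[1], fit_band[2])
  fit <- stats::lm.fit(cbind(1, r$wavelength_nm[inband]), loginv[inband])
  a <- fit$coefficients[1]; m <- fit$coefficients[2]
  structure(list(wavelength_nm = r$wavelength_nm,
                 a_corr = loginv - (a + m * r$wavelength_nm),
                 baseline_intercept = unname(a), baseline_slope = unname(m),
                 fit_band = fit_band),
            class = "corrected_absorbance")
}

# Nearest-node read of a corrected-absorbance curve (0.5 nm tolerance).
ca_value_at <- function(ca, wl, tol_nm = 0.5) {
  vapply(wl, function(w) {
    i <- which.min(abs(ca$wavelength_nm - w))
    if (abs(ca$wavelength_nm[i] - w) > tol_nm)
      stop_range("wavelength %.1f nm not on the absorbance grid", w)
    ca$a_corr[i]
  }, numeric(1))
}

#' Two-wavelength analytic StO2
#'
#' Solves the 2x2 system A(lambda_i) = eps_Hb(lambda_i) x_Hb +
#' eps_HbO2(lambda_i) x_HbO2 at the wavelength pair (default 555 and
#' 575 nm), where x = C <L> is the path-scaled concentration; the unknown
#' average path length <L> cancels in StO2 = x_HbO2 / (x_Hb + x_HbO2).
#' Negative components (noise at low hemoglobin content) are clamped to zero
#' and flagged.
#'
#' @param ca a [corrected_absorbance].
#' @param table an [extinction_table].
#' @param wavelengths the wavelength pair (nm).
#' @return list with `x_hb`, `x_hbo2` (mol/L cm), `sto2`, `clamped` flag,
#'   and `sto2_defined` (FALSE when both components vanish).
#' @export
sto2_two_wavelength <- function(ca, table = load_extinction(),
                                wavelengths = c(555, 575)) {
  stopifnot(inherits(ca, "corrected_absorbance"))
  tb <- resample_extinction(table, wavelengths)
  E <- cbind(tb$eps_hb, tb$eps_hbo2)
  if (kappa(E, exact = TRUE) > 1e6)
    stop_domain("extinction matrix at %.0f/%.0f nm is near-singular",
                wavelengths[1], wavelengths[2])
  Avec <- ca_value_at(ca, wavelengths)
  x <- solve(E, Avec)
  clamped <- any(x < 0)
  x <- pmax(x, 0)
  tot <- x[1] + x[2]
  list(x_hb = x[1], x_hbo2 = x[2],
       sto2 = if (tot > 0) x[2] / tot else NA_real_,
       sto2_defined = tot > 0, clamped = clamped,
       wavelengths = wavelengths)
}

#' Isosbestic reflectance ratio indicating total hemoglobin
#'
#' R(584)/R(545): both wavelengths sit at near-isosbestic crossings of the
#' extinction table, so the ratio tracks total hemoglobin while being almost
#' insensitive to oxygen saturation. Optionally each value is the mean over
#' a small +/- `half_width_nm` band.
#'
#' @param r a reflectance [spectrum].
#' @param wavelengths `c(numerator, denominator)` nm.
#' @param half_width_nm 0 for single 1-nm node values (default), or a small
#'   half-width for band means.
#' @return the ratio (dimensionless).
#' @export
thb_ratio <- function(r, wavelengths = c(584, 545), half_width_nm = 0) {
  stopifnot(is_spectrum(r))
  val <- function(w) {
    if (half_width_nm <= 0) return(spectrum_value_at(r, w))
    keep <- abs(r$wavelength_nm - w) <= half_width_nm
    if (!any(keep)) stop_range("no samples within %.1f nm of %.1f nm",
                               half_width_nm, w)
    mean(r$value[keep])
  }
  num <- val(wavelengths[1]); den <- val(wavelengths[2])
  if (den <= 0) stop_domain("reflectance at %.0f nm must be > 0", wavelengths[2])
  num / den
}

#' Calibrate the hemoglobin ratio against known concentrations
#'
#' Least-squares fit of true \[THB\] on the 584/545 reflectance ratio over a
#' phantom set (linear by default, quadratic available). Refuses a fitted
#' mapping that is non-monotone over the calibrated ratio range.
#'
#' @param ratio,thb_mg_per_ml paired observations (>= 3, thb not all equal).
#' @param model `"linear"` or `"quadratic"`.
#' @param channel_id channel the calibration belongs to.
#' @return An object of class `thb_calibration`: coefficients, `r_squared`,
#'   `range` of calibrated ratios, `model`, `channel_id`.
#' @export
calibrate_thb <- function(ratio, thb_mg_per_ml,
                          model = c("linear", "quadratic"), channel_id = 1) {
  model <- match.arg(model)
  if (length(ratio) != length(thb_mg_per_ml) || length(ratio) < 3)
    stop_validation("calibration needs >= 3 (ratio, thb) pairs")
  if (stats::sd(thb_mg_per_ml) == 0)
    stop_validation("thb values must not all be equal")
  X <- if (model == "linear") cbind(1, ratio) else cbind(1, ratio, ratio^2)
  fit <- stats::lm.fit(X, thb_mg_per_ml)
  coefs <- unname(fit$coefficients)
  r2 <- 1 - sum(fit$residuals^2) / sum((thb_mg_per_ml - mean(thb_mg_per_ml))^2)
  rng <- range(ratio)
  grid <- seq(rng[1], rng[2], length.out = 101)
  deriv <- if (model == "linear") rep(coefs[2], 101) else coefs[2] + 2 * coefs[3] * grid
  if (any(deriv >= 0) && any(deriv <= 0))
    stop_validation("fitted calibration is non-monotone over the data range")
  structure(list(model = model, coefficients = coefs, r_squared = r2,
                 range = rng, channel_id = channel_id,
                 ratio_wavelengths = c(584, 545)),
            class = "thb_calibration")
}

#' @export
print.thb_calibration <- function(x, ...) {
  cat(sprintf("<thb_calibration: %s, ch %d, R^2 %.4f, ratios %.3f-%.3f>\n",
              x$model, x$channel_id, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Apply a hemoglobin ratio calibration
#'
#' Evaluates the stored model at a new ratio. Ratios beyond 1.2x outside the
#' calibrated range are still evaluated but flagged as extrapolation.
#'
#' @param cal a [thb_calibration].
#' @param ratio observed ratio(s).
#' @return numeric thb estimate(s) (mg/mL) with attribute
#'   `"extrapolated"` (logical per value).
#' @export
apply_thb_calibration <- function(cal, ratio) {
  stopifnot(inherits(cal, "thb_calibration"))
  co <- cal$coefficients
  est <- if (cal$model == "linear") co[1] + co[2] * ratio
         else co[1] + co[2] * ratio + co[3] * ratio^2
  width <- diff(cal$range)
  guard_lo <- cal$range[1] - 0.2 * width
  guard_hi <- cal$range[2] + 0.2 * width
  flag <- ratio < guard_lo | ratio > guard_hi
  if (any(flag))
    warning("ratio outside the calibration guard band; estimate extrapolated")
  attr(est, "extrapolated") <- flag
  est
}

# --- persistence: small delimited text record ---

#' Write / read a hemoglobin calibration file
#'
#' One-record delimited text (model order, coefficients, R^2, ratio range,
#' channel), so a phantom calibration can be reused across sessions.
#'
#' @param cal a [thb_calibration].
#' @param path file path.
#' @return `read_thb_calibration` returns a [thb_calibration].
#' @export
write_thb_calibration <- function(cal, path) {
  co <- c(cal$coefficients, rep(NA_real_, 3 - length(cal$coefficients)))
  df <- data.frame(model = cal$model, c0 = co[1], c1 = co[2], c2 = co[3],
                   r_squared = cal$r_squared, ratio_min = cal$range[1],
                   ratio_max = cal$range[2], channel_id = cal$channel_id)
  utils::write.table(format(df, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thb_calibration
#' @export
read_thb_calibration <- function(path) {
  if (!file.exists(path)) stop_validation("calibration file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  coefs <- as.numeric(df[1, c("c0", "c1", "c2")])
  coefs <- coefs[!is.na(coefs)]
  structure(list(model = df$model[1], coefficients = coefs,
                 r_squared = df$r_squared[1],
                 range = c(df$ratio_min[1], df$ratio_max[1]),
                 channel_id = df$channel_id[1],
                 ratio_wavelengths = c(584, 545)),
            class = "thb_calibration")
}
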