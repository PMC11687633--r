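#' Hemoglobin state of a sample
#'
#' Total hemoglobin mass concentration plus oxygen saturation. The molar mass
#' default (64,500 g/mol, the standard tetramer value) converts mg/mL phantom
#' concentrations to molarity.
#'
#' @param thb_mg_per_ml total hemoglobin (mg/mL), >= 0.
#' @param so2 oxygen saturation fraction in \[0, 1\].
#' @param molar_mass_g_per_mol hemoglobin molar mass (g/mol).
#' @return An object of class `hemoglobin_state`.
#' @export
hemoglobin_state <- function(thb_mg_per_ml, so2,
                             molar_mass_g_per_mol = 64500) {
  if (!is.finite(thb_mg_per_ml) || thb_mg_per_ml < 0)
    stop_validation("thb_mg_per_ml must be finite and >= 0 (got %s)",
                    format(thb_mg_per_ml))
  if (!is.finite(so2) || so2 < 0 || so2 > 1)
    stop_validation("so2 must lie in [0, 1] (got %s)", format(so2))
  if (molar_mass_g_per_mol <= 0)
    stop_validation("molar mass must be positive")
  structure(list(thb_mg_per_ml = thb_mg_per_ml, so2 = so2,
                 molar_mass_g_per_mol = molar_mass_g_per_mol),
            class = "hemoglobin_state")
}

#' Absorption spectrum of a hemoglobin solution
#'
#' mu_a(lambda) = ln(10) * (C_HbO2 * eps_HbO2 + C_Hb * eps_Hb) with molar
#' concentrations C_HbO2 = so2 * thb / M and C_Hb = (1 - so2) * thb / M.
#' The ln(10) factor reflects the base-10 extinction convention of the
#' bundled table; the same convention is used everywhere (unmixing, the
#' two-wavelength solve), which is what recovery tests require.
#'
#' @param state a [hemoglobin_state].
#' @param table an [extinction_table].
#' @param grid wavelengths (nm) within the table span.
#' @return numeric mu_a (cm^-1) on `grid`.
#' @export
mua_from_hemoglobin <- function(state, table, grid) {
  stopifnot(inherits(state, "hemoglobin_state"),
            inherits(table, "extinction_table"))
  tb <- resample_extinction(table, grid)
  c_tot <- state$thb_mg_per_ml / state$molar_mass_g_per_mol  # g/L / (g/mol) = mol/L
  c_hbo2 <- c_tot * state$so2
  c_hb <- c_tot * (1 - state$so2)
  log(10) * (c_hbo2 * tb$eps_hbo2 + c_hb * tb$eps_hb)
}

#' Reduced scattering spectrum from a scatter power law
#'
#' mu_s'(lambda) = amplitude * (lambda / ref_wavelength)^(-exponent), the
#' standard parameterization for polystyrene-sphere or tissue-like scattering.
#'
#' @param amplitude mu_s' at the reference wavelength (cm^-1), > 0.
#' @param exponent scattering power (dimensionless, >= 0 in practice).
#' @param grid wavelengths (nm).
#' @param ref_wavelength_nm reference wavelength (nm).
#' @return numeric mu_s' (cm^-1) on `grid`.
#' @export
musp_power_law <- function(amplitude, exponent, grid,
                           ref_wavelength_nm = 550) {
  if (!is.finite(amplitude) || amplitude <= 0)
    stop_validation("scatter amplitude must be > 0 (got %s)", format(amplitude))
  amplitude * (grid / ref_wavelength_nm)^(-exponent)
}

#' Scatter amplitude hitting a target band-mean mu_s'
#'
#' Solves for the power-law amplitude whose 400-600 nm average equals
#' `target_mean` (how the phantom designs pin their scattering levels of 10
#' and 20 cm^-1).
#'
#' @param target_mean desired band-mean mu_s' (cm^-1).
#' @param exponent scattering power.
#' @param band averaging band `c(lo, hi)` nm.
#' @param ref_wavelength_nm reference wavelength (nm).
#' @return amplitude (cm^-1) at the reference wavelength.
#' @export
musp_amplitude_for_band_mean <- function(target_mean, exponent,
                                         band = c(400, 600),
                                         ref_wavelength_nm = 550) {
  if (target_mean <= 0) stop_validation("target band mean must be > 0")
  grid <- seq(band[1], band[2], by = 1)
  target_mean / mean((grid / ref_wavelength_nm)^(-exponent))
}

#' Hemoglobin concentration hitting a target band-mean mu_a
#'
#' Inverse of the (linear-in-thb) band mean of [mua_from_hemoglobin]; used by
#' the fluorescence phantom design, which is specified by its mean absorption
#' levels rather than by hemoglobin content.
#'
#' @param target_mean desired 400-600 nm mean mu_a (cm^-1).
#' @param so2 oxygen saturation of the phantom hemoglobin.
#' @param table an [extinction_table].
#' @param band averaging band `c(lo, hi)` nm.
#' @return thb (mg/mL).
#' @export
thb_for_band_mean_mua <- function(target_mean, so2, table,
                                  band = c(400, 600)) {
  grid <- seq(band[1], band[2], by = 1)
  unit <- mean(mua_from_hemoglobin(hemoglobin_state(1, so2), table, grid))
  target_mean / unit
}
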