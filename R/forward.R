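#' Fiber-probe geometry
#'
#' Two collection channels: channel 1 averages a 1.5 mm source-detector
#' separation (shallow sensing), channel 2 averages 3.0 mm (deeper sensing);
#' 200 um fibers.
#'
#' @param channel_id 1 or 2.
#' @param sds_mm source-detector separation (mm); defaults by channel.
#' @param fiber_diameter_um fiber diameter (um).
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(channel_id = 1, sds_mm = NULL,
                           fiber_diameter_um = 200) {
  if (!channel_id %in% c(1, 2))
    stop_validation("channel_id must be 1 or 2 (got %s)", format(channel_id))
  if (is.null(sds_mm)) sds_mm <- c(`1` = 1.5, `2` = 3.0)[[as.character(channel_id)]]
  if (sds_mm <= 0) stop_validation("sds_mm must be > 0")
  structure(list(channel_id = channel_id, sds_mm = sds_mm,
                 fiber_diameter_um = fiber_diameter_um),
            class = "probe_geometry")
}

#' Bulk optical properties of a turbid medium
#'
#' Absorption and reduced scattering spectra on a shared wavelength grid.
#'
#' @param wavelength_nm strictly increasing grid (nm).
#' @param mua absorption coefficient spectrum (cm^-1), >= 0.
#' @param musp reduced scattering spectrum (cm^-1), > 0.
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(wavelength_nm, mua, musp) {
  n <- length(wavelength_nm)
  if (length(mua) != n || length(musp) != n)
    stop_validation("wavelength, mua and musp must have equal lengths")
  if (any(diff(wavelength_nm) <= 0))
    stop_validation("wavelength grid must be strictly increasing")
  if (any(!is.finite(mua)) || any(mua < 0))
    stop_validation("mua must be finite and >= 0")
  if (any(!is.finite(musp)) || any(musp <= 0))
    stop_validation("musp must be finite and > 0")
  structure(list(wavelength_nm = wavelength_nm, mua = as.numeric(mua),
                 musp = as.numeric(musp)),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties: %d wavelengths, %.0f-%.0f nm, band-mean mua %.2f, musp %.2f cm^-1>\n",
              length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
              band_mean(x, "mua"), band_mean(x, "musp")))
  invisible(x)
}

#' Band-mean of an optical property
#'
#' Mean of mu_a or mu_s' over a wavelength band (default 400-600 nm, the
#' band in which phantom absorption/scattering levels are defined).
#'
#' @param props an [optical_properties].
#' @param which `"mua"` or `"musp"`.
#' @param band `c(lo, hi)` nm.
#' @return scalar mean (cm^-1).
#' @export
band_mean <- function(props, which = c("mua", "musp"), band = c(400, 600)) {
  which <- match.arg(which)
  keep <- props$wavelength_nm >= band[1] & props$wavelength_nm <= band[2]
  if (!any(keep)) stop_range("band %.0f-%.0f nm not on the property grid",
                             band[1], band[2])
  mean(props[[which]][keep])
}

#' Forward reflectance kernels
#'
#' Two interchangeable semi-infinite forward models sit behind every
#' simulation and inversion in the package:
#' \describe{
#'   \item{`"short_sds"` (default)}{An empirical sub-diffuse modified
#'     Beer-Lambert kernel, R = S(mu_s', rho) exp(-mu_a L(mu_s', rho)), with
#'     a scattering-only escape factor S = x/(1+x)/(4 pi rho^2),
#'     x = (mu_s' rho)^1.3, and an absorption-independent effective path
#'     L = rho (1.8 + 0.15 mu_s' rho). At millimeter separations comparable
#'     to the transport mean free path, detected photons follow
#'     geometry-dominated banana paths whose length depends only weakly on
#'     absorption and scattering; the constants give differential path-length
#'     factors near 2, the regime in which short-separation reflectance
#'     probes (and the corrected-absorbance algebra) operate.}
#'   \item{`"diffusion"`}{The steady-state diffusion-approximation dipole
#'     with extrapolated boundary, evaluated at radial distance rho. The
#'     textbook far-field model; at 1.5 mm with mu_a up to 7.5 cm^-1 its
#'     effective path length varies strongly with absorption, which is
#'     outside the regime the analytic estimators assume.}
#' }
#' Both are deterministic, smooth, strictly decreasing in mu_a, and decay
#' with rho. Simulation and inversion always share the chosen kernel, so
#' round-trip recovery is well-posed under either.
#'
#' @param mua,musp absorption / reduced scattering (cm^-1), vectorized.
#' @param rho_cm source-detector separation (cm).
#' @param model kernel name.
#' @return reflectance values (calibrated instrument units).
#' @export
forward_reflectance <- function(mua, musp, rho_cm,
                                model = c("short_sds", "diffusion")) {
  model <- match.arg(model)
  if (any(mua + musp <= 0)) stop_model("transport coefficient must be positive")
  if (model == "short_sds") {
    x <- (musp * rho_cm)^1.3
    S <- x / (1 + x) / (4 * pi * rho_cm^2)
    L <- rho_cm * (1.8 + 0.15 * musp * rho_cm)
    S * exp(-mua * L)
  } else {
    diffusion_reflectance(mua, musp, rho_cm)
  }
}

# Diffusion-approximation dipole (extrapolated boundary), semi-infinite
# medium, radial distance rho. Vectorized over mua/musp.
diffusion_reflectance <- function(mua, musp, rho_cm, n_rel = 1.4) {
  mut <- mua + musp
  if (any(mut <= 0)) stop_model("transport coefficient must be positive")
  D <- 1 / (3 * mut)
  z0 <- 1 / mut
  r_eff <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  A <- (1 + r_eff) / (1 - r_eff)
  zb <- 2 * A * D
  mueff <- sqrt(3 * mua * mut)
  r1 <- sqrt(z0^2 + rho_cm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_cm^2)
  (1 / (4 * pi)) * (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
                    (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
}

#' Simulate a calibrated diffuse reflectance spectrum
#'
#' Evaluates the configured semi-infinite forward kernel at the probe's
#' source-detector separation, wavelength by wavelength. Noise-free; see
#' [add_noise].
#'
#' @param props an [optical_properties] whose grid covers 450-650 nm.
#' @param geom a [probe_geometry].
#' @param model forward kernel name (see [forward_reflectance]).
#' @return A reflectance [spectrum] on the property grid.
#' @export
simulate_reflectance <- function(props, geom = probe_geometry(1),
                                 model = c("short_sds", "diffusion")) {
  model <- match.arg(model)
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "probe_geometry"))
  if (min(props$wavelength_nm) > 450 || max(props$wavelength_nm) < 650)
    stop_range("property grid must cover 450-650 nm")
  if (all(props$mua == 0) && max(props$musp) < 1)
    stop_model("no diffuse regime: mua = 0 with negligible scattering")
  r <- forward_reflectance(props$mua, props$musp, geom$sds_mm / 10, model)
  spectrum(props$wavelength_nm, r, "reflectance",
           meta = list(channel = geom$channel_id, sds_mm = geom$sds_mm))
}

#' Fluorophore conventions
#'
#' Excitation source peaks (bandpass filter centers), emission lineshape
#' peaks, and acquisition windows for the two metabolic probes: the glucose
#' analog ("NBDG") and the mitochondrial probe ("TMRE"). Lineshapes are
#' Gaussian (peak 545 nm / FWHM 40 nm and peak 580 nm / FWHM 35 nm), clipped
#' to the acquisition windows 520-600 and 565-650 nm.
#'
#' @param fluorophore `"NBDG"` or `"TMRE"`.
#' @return A list with `excitation_nm`, `emission_peak_nm`, `window_nm`,
#'   `fwhm_nm`, and `conc_unit`.
#' @export
fluorophore_info <- function(fluorophore = c("NBDG", "TMRE")) {
  fluorophore <- match.arg(fluorophore)
  switch(fluorophore,
    NBDG = list(fluorophore = "NBDG", excitation_nm = 450,
                emission_peak_nm = 545, window_nm = c(520, 600),
                fwhm_nm = 40, conc_unit = "uM"),
    TMRE = list(fluorophore = "TMRE", excitation_nm = 550,
                emission_peak_nm = 580, window_nm = c(565, 650),
                fwhm_nm = 35, conc_unit = "nM"))
}

# Unit emission lineshape on a grid, clipped to the acquisition window.
fluor_lineshape <- function(fluorophore, grid) {
  fi <- fluorophore_info(fluorophore)
  s <- fi$fwhm_nm / (2 * sqrt(2 * log(2)))
  y <- exp(-0.5 * ((grid - fi$emission_peak_nm) / s)^2)
  y[grid < fi$window_nm[1] | grid > fi$window_nm[2]] <- 0
  y
}

# Transport weight of the medium at one wavelength: the forward-model
# reflectance at the probe separation, evaluated at that wavelength's
# optical properties (nearest grid node, 0.5 nm tolerance).
transport_weight <- function(props, geom, wl, model = "short_sds") {
  vapply(wl, function(w) {
    i <- which.min(abs(props$wavelength_nm - w))
    if (abs(props$wavelength_nm[i] - w) > 0.5)
      stop_range("wavelength %.1f nm not on the property grid", w)
    forward_reflectance(props$mua[i], props$musp[i], geom$sds_mm / 10, model)
  }, numeric(1))
}

#' Simulate a distorted fluorescence spectrum
#'
#' Born-type product model: emitted intensity = concentration x unit emission
#' lineshape x excitation transport weight (at the excitation filter peak) x
#' emission escape weight (at each emission wavelength), both weights taken
#' from the same forward model as [simulate_reflectance]. This produces
#' exactly the absorption/scattering distortion class that the ratio-metric
#' correction is designed to remove. Noise-free and linear in concentration.
#'
#' @param props an [optical_properties] covering the excitation peak and the
#'   emission window.
#' @param fluorophore `"NBDG"` or `"TMRE"`.
#' @param conc fluorophore concentration (uM for NBDG, nM for TMRE), >= 0.
#' @param geom a [probe_geometry].
#' @param model forward kernel name (see [forward_reflectance]).
#' @return A fluorescence [spectrum] on the acquisition window.
#' @export
simulate_fluorescence <- function(props, fluorophore, conc,
                                  geom = probe_geometry(1),
                                  model = c("short_sds", "diffusion")) {
  model <- match.arg(model)
  stopifnot(inherits(props, "optical_properties"))
  fi <- fluorophore_info(fluorophore)
  if (!is.finite(conc) || conc < 0)
    stop_validation("fluorophore concentration must be >= 0")
  if (min(props$wavelength_nm) > fi$window_nm[1] ||
      max(props$wavelength_nm) < fi$window_nm[2])
    stop_range("property grid must cover the %s emission window %.0f-%.0f nm",
               fi$fluorophore, fi$window_nm[1], fi$window_nm[2])
  keep <- props$wavelength_nm >= fi$window_nm[1] &
    props$wavelength_nm <= fi$window_nm[2]
  grid <- props$wavelength_nm[keep]
  w_ex <- transport_weight(props, geom, fi$excitation_nm, model)
  w_em <- forward_reflectance(props$mua[keep], props$musp[keep],
                              geom$sds_mm / 10, model)
  value <- conc * fluor_lineshape(fluorophore, grid) * w_ex * w_em
  spectrum(grid, value, "fluorescence",
           meta = list(channel = geom$channel_id, fluorophore = fi$fluorophore,
                       conc = conc, conc_unit = fi$conc_unit))
}
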