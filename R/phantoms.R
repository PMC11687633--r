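#' Phantom recipe
#'
#' One tissue-mimicking phantom: a hemoglobin state, a scatter power law, an
#' optional fluorophore at a given concentration, a multiplicative noise
#' level, and a seed.
#'
#' @param hemoglobin a [hemoglobin_state].
#' @param scatter_amplitude,scatter_exponent power-law parameters
#'   (amplitude at 550 nm, cm^-1).
#' @param fluorophore `"none"`, `"NBDG"` or `"TMRE"`.
#' @param fluorophore_conc concentration (uM for NBDG, nM for TMRE).
#' @param noise_sd_frac multiplicative Gaussian noise SD as a fraction.
#' @param seed integer RNG seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(hemoglobin, scatter_amplitude, scatter_exponent,
                         fluorophore = "none", fluorophore_conc = 0,
                         noise_sd_frac = 0.01, seed = 1L) {
  stopifnot(inherits(hemoglobin, "hemoglobin_state"))
  if (!fluorophore %in% c("none", "NBDG", "TMRE"))
    stop_validation("fluorophore must be none, NBDG or TMRE")
  if (fluorophore_conc < 0) stop_validation("fluorophore_conc must be >= 0")
  if (noise_sd_frac < 0) stop_validation("noise_sd_frac must be >= 0")
  if (scatter_amplitude <= 0) stop_validation("scatter_amplitude must be > 0")
  structure(list(hemoglobin = hemoglobin,
                 scatter_amplitude = scatter_amplitude,
                 scatter_exponent = scatter_exponent,
                 fluorophore = fluorophore,
                 fluorophore_conc = fluorophore_conc,
                 noise_sd_frac = noise_sd_frac, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Optical properties implied by a phantom recipe
#'
#' @param spec a [phantom_spec].
#' @param table an [extinction_table].
#' @param grid wavelength grid (nm).
#' @return An [optical_properties].
#' @export
phantom_properties <- function(spec, table = load_extinction(),
                               grid = 400:680) {
  mua <- mua_from_hemoglobin(spec$hemoglobin, table, grid)
  musp <- musp_power_law(spec$scatter_amplitude, spec$scatter_exponent, grid)
  optical_properties(grid, mua, musp)
}

#' Add multiplicative measurement noise to a spectrum
#'
#' value -> value * (1 + e), e ~ Normal(0, noise_sd_frac), clipped at zero.
#' Reproducible given `seed`; the caller's RNG state is left untouched.
#'
#' @param s a [spectrum].
#' @param noise_sd_frac noise SD as a fraction of the signal (>= 0).
#' @param seed integer seed.
#' @return A [spectrum] of the same kind and metadata.
#' @export
add_noise <- function(s, noise_sd_frac, seed = 1L) {
  stopifnot(is_spectrum(s))
  if (noise_sd_frac < 0) stop_validation("noise_sd_frac must be >= 0")
  if (noise_sd_frac == 0) return(s)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eps <- stats::rnorm(length(s$value), 0, noise_sd_frac)
  spectrum(s$wavelength_nm, pmax(0, s$value * (1 + eps)), s$kind, s$meta)
}

# Deterministic per-phantom sub-seed derived from a run seed (kept < 2^31).
sub_seed <- function(seed, i) (as.integer(seed) * 1009L + 97L * as.integer(i)) %% 2147483647L

#' Simulate a phantom study
#'
#' The synthetic test bed standing in for the instrument. Two designs:
#' \describe{
#'   \item{`"reflectance"`}{2 scattering levels (band-mean mu_s' of 10 and
#'     20 cm^-1 over 400-600 nm) x 7 hemoglobin additions (0.9-6.3 mg/mL in
#'     equal steps; the seven individual values are not published, equal
#'     spacing is this package's choice) = 14 phantoms, each measured by both
#'     channels. Band-mean mu_a spans roughly 1.0-7.5 cm^-1.}
#'   \item{`"fluorescence"`}{3 absorption levels (band-mean mu_a 1.5, 3.0,
#'     4.5 cm^-1) x 2 scattering levels (10, 20 cm^-1) x 3 concentrations
#'     (2/4/6 uM NBDG or 30/60/90 nM TMRE) = 18 phantoms per fluorophore,
#'     each with a paired reflectance spectrum per channel.}
#' }
#' The manifest records the simulation inputs (never re-estimated): true
#' hemoglobin, saturation, band-mean optical properties, concentrations.
#'
#' @param design `"reflectance"` or `"fluorescence"`.
#' @param seed integer run seed; every noise draw derives from it.
#' @param fluorophore for the fluorescence design, `"NBDG"` or `"TMRE"`.
#' @param noise_sd_frac multiplicative noise level (default 0.01, the
#'   realistic study condition; pass 0 for exactness tests).
#' @param so2 phantom oxygen saturation (default 1: hemoglobin in aerated
#'   water is essentially fully oxygenated).
#' @param scatter_exponent scatter power-law exponent.
#' @param table an [extinction_table].
#' @param grid simulation wavelength grid (nm).
#' @return A list with `phantoms` (list of records: `spec`, per-channel
#'   `reflectance`, and for the fluorescence design per-channel
#'   `fluorescence`) and `manifest` (data.frame of ground truth).
#' @export
make_phantom_set <- function(design = c("reflectance", "fluorescence"),
                             seed = 1L, fluorophore = "TMRE",
                             noise_sd_frac = 0.01, so2 = 1,
                             scatter_exponent = 1.0,
                             table = load_extinction(), grid = 400:680) {
  design <- match.arg(design)
  musp_levels <- c(10, 20)
  amps <- vapply(musp_levels, musp_amplitude_for_band_mean,
                 numeric(1), exponent = scatter_exponent)
  geoms <- list(ch1 = probe_geometry(1), ch2 = probe_geometry(2))

  if (design == "reflectance") {
    thb_levels <- seq(0.9, 6.3, length.out = 7)
    combos <- expand.grid(musp_i = 1:2, thb = thb_levels)
  } else {
    mua_levels <- c(1.5, 3.0, 4.5)
    conc_levels <- if (fluorophore == "NBDG") c(2, 4, 6) else c(30, 60, 90)
    combos <- expand.grid(musp_i = 1:2, mua = mua_levels, conc = conc_levels)
  }

  phantoms <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    co <- combos[i, ]
    thb <- if (design == "reflectance") co$thb else
      thb_for_band_mean_mua(co$mua, so2, table)
    hb <- hemoglobin_state(thb, so2)
    sp <- phantom_spec(hb, amps[co$musp_i], scatter_exponent,
                       fluorophore = if (design == "fluorescence") fluorophore else "none",
                       fluorophore_conc = if (design == "fluorescence") co$conc else 0,
                       noise_sd_frac = noise_sd_frac, seed = sub_seed(seed, i))
    props <- phantom_properties(sp, table, grid)
    rec <- list(spec = sp, props = props)
    for (ch in names(geoms)) {
      r <- simulate_reflectance(props, geoms[[ch]])
      rec$reflectance[[ch]] <-
        add_noise(r, noise_sd_frac, sub_seed(sp$seed, match(ch, names(geoms))))
      if (design == "fluorescence") {
        f <- simulate_fluorescence(props, fluorophore, co$conc, geoms[[ch]])
        rec$fluorescence[[ch]] <-
          add_noise(f, noise_sd_frac, sub_seed(sp$seed, 10L + match(ch, names(geoms))))
      }
    }
    phantoms[[i]] <- rec
    rows[[i]] <- data.frame(
      id = i, design = design,
      fluorophore = sp$fluorophore, fluorophore_conc = sp$fluorophore_conc,
      thb_mg_per_ml = thb, so2 = so2,
      scatter_amplitude = amps[co$musp_i], scatter_exponent = scatter_exponent,
      mean_mua_400_600 = band_mean(props, "mua"),
      mean_musp_400_600 = band_mean(props, "musp"),
      noise_sd_frac = noise_sd_frac, seed = sp$seed)
  }
  list(phantoms = phantoms, manifest = do.call(rbind, rows))
}

#' Closed-form peak time of the two-rate uptake model
#'
#' For I(t) = A (1 - exp(-k_in t)) exp(-k_out t), the interior maximum sits
#' at t* = ln(1 + k_in / k_out) / k_in (post-injection time).
#'
#' @param k_in,k_out uptake and washout rates (1/min), positive.
#' @return peak time (min); `Inf` when `k_out = 0` (saturating trace).
#' @export
kinetic_peak_time <- function(k_in, k_out) {
  if (k_in <= 0) stop_validation("k_in must be > 0")
  if (k_out < 0) stop_validation("k_out must be >= 0")
  if (k_out == 0) return(Inf)
  log(1 + k_in / k_out) / k_in
}

#' Simulate a probe-uptake kinetic trace
#'
#' Two-rate uptake model I(t) = A (1 - e^(-k_in (t - t0))) e^(-k_out (t - t0))
#' for t >= t0 and 0 before, on the experiment clock: the mitochondrial probe
#' is injected at t0 = 0 and the glucose analog at t0 = 20 min (the
#' experimental injection delay).
#'
#' @param fluorophore `"NBDG"` or `"TMRE"`.
#' @param amplitude,k_in,k_out model parameters (`k_in > 0`, `k_out >= 0`).
#' @param times_min sampling times on the experiment clock, within
#'   \[0, 80\] min, strictly increasing.
#' @param noise_sd_frac multiplicative noise level.
#' @param seed integer seed for the noise draw.
#' @return A [kinetic_trace] (times stored relative to injection).
#' @export
simulate_kinetic_trace <- function(fluorophore, amplitude = 1,
                                   k_in = 0.15, k_out = 0.01,
                                   times_min = seq(0, 80, by = 2),
                                   noise_sd_frac = 0, seed = 1L) {
  if (k_in <= 0 || k_out < 0)
    stop_validation("rates must satisfy k_in > 0, k_out >= 0")
  if (amplitude < 0) stop_validation("amplitude must be >= 0")
  if (any(times_min < 0) || any(times_min > 80) || any(diff(times_min) <= 0))
    stop_validation("times must lie in [0, 80] min and be strictly increasing")
  t0 <- if (fluorophore == "NBDG") 20 else 0
  tt <- pmax(0, times_min - t0)
  intensity <- amplitude * (1 - exp(-k_in * tt)) * exp(-k_out * tt)
  if (noise_sd_frac > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    intensity <- pmax(0, intensity * (1 + stats::rnorm(length(intensity), 0, noise_sd_frac)))
  }
  kinetic_trace(times_min - t0, intensity, fluorophore)
}
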