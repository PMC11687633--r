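# Ratio-metric intrinsic-fluorescence correction: divide the raw emission by
# powers of the diffuse reflectance at the excitation and emission peaks,
# with the power pair optimized on a fluorescence phantom grid. The
# model-divide route (dividing by the forward model's attenuation factor at
# inverted optical properties) is the benchmark the ratio method is held to.

#' Correction context: reflectance at the excitation and emission peaks
#'
#' Reads R_ex (at the excitation filter peak: 450 nm for the glucose analog,
#' 550 nm for the mitochondrial probe) and R_em (at the configured emission
#' peak) off the calibrated reflectance spectrum measured on the same sample.
#'
#' @param reflectance a reflectance [spectrum] of the same sample.
#' @param fluorophore `"NBDG"` or `"TMRE"`.
#' @param emission_peak_nm emission peak (nm); defaults to the fluorophore's
#'   configured peak.
#' @return An object of class `correction_context`: `r_ex`, `r_em`,
#'   `excitation_nm`, `emission_peak_nm`, `fluorophore`.
#' @export
correction_context <- function(reflectance, fluorophore,
                               emission_peak_nm = NULL) {
  stopifnot(is_spectrum(reflectance))
  if (reflectance$kind != "reflectance")
    stop_validation("correction_context needs a reflectance spectrum")
  fi <- fluorophore_info(fluorophore)
  if (is.null(emission_peak_nm)) emission_peak_nm <- fi$emission_peak_nm
  r_ex <- spectrum_value_at(reflectance, fi$excitation_nm)
  r_em <- spectrum_value_at(reflectance, emission_peak_nm)
  if (r_ex <= 0 || r_em <= 0)
    stop_domain("reflectance at the correction wavelengths must be > 0")
  structure(list(r_ex = r_ex, r_em = r_em,
                 excitation_nm = fi$excitation_nm,
                 emission_peak_nm = emission_peak_nm,
                 fluorophore = fi$fluorophore),
            class = "correction_context")
}

#' Correction power pair
#'
#' The system-dependent exponents (alpha, beta) applied to R_ex and R_em.
#' Powers are stored per (fluorophore, channel); they must not be shared
#' across channels.
#'
#' @param alpha,beta exponents (finite).
#' @param fluorophore `"NBDG"` or `"TMRE"`.
#' @param channel_id collection channel.
#' @param objective_value objective at the optimum (>= 0), if optimized.
#' @param converged optimizer convergence flag.
#' @return An object of class `correction_powers`.
#' @export
correction_powers <- function(alpha, beta, fluorophore = "TMRE",
                              channel_id = 1, objective_value = NA_real_,
                              converged = NA) {
  if (!is.finite(alpha) || !is.finite(beta))
    stop_validation("correction powers must be finite")
  structure(list(alpha = alpha, beta = beta, fluorophore = fluorophore,
                 channel_id = channel_id, objective_value = objective_value,
                 converged = converged),
            class = "correction_powers")
}

#' @export
print.correction_powers <- function(x, ...) {
  cat(sprintf("<correction_powers: %s ch %d, alpha %.4f, beta %.4f, objective %.3g>\n",
              x$fluorophore, x$channel_id, x$alpha, x$beta, x$objective_value))
  invisible(x)
}

#' Ratio-metric intrinsic-fluorescence correction
#'
#' F_corr(lambda) = F_raw(lambda) / (R_ex^alpha R_em^beta): a
#' wavelength-uniform rescaling whose sample-specific magnitude cancels the
#' absorption/scattering distortion of the raw emission.
#'
#' @param f_raw a fluorescence [spectrum].
#' @param ctx a [correction_context] from the paired reflectance.
#' @param powers a [correction_powers].
#' @return The corrected fluorescence [spectrum].
#' @export
correct_fluorescence <- function(f_raw, ctx, powers) {
  stopifnot(is_spectrum(f_raw), inherits(ctx, "correction_context"),
            inherits(powers, "correction_powers"))
  if (f_raw$kind != "fluorescence")
    stop_validation("correct_fluorescence needs a fluorescence spectrum")
  if (ctx$r_ex <= 0 || ctx$r_em <= 0)
    stop_domain("correction context reflectances must be > 0")
  scale <- ctx$r_ex^powers$alpha * ctx$r_em^powers$beta
  meta <- f_raw$meta
  meta$corrected <- "ratiometric"
  spectrum(f_raw$wavelength_nm, f_raw$value / scale, "fluorescence", meta)
}

#' Mean intensity over the emission peak band
#'
#' Arithmetic mean of the values with wavelength within
#' `peak_nm +/- half_width_nm` (inclusive) - the scalar every downstream
#' endpoint (kinetic traces, linearity fits) is built from.
#'
#' @param s a [spectrum].
#' @param peak_nm band center (nm).
#' @param half_width_nm band half width (nm).
#' @return scalar mean intensity.
#' @export
peak_band_mean <- function(s, peak_nm, half_width_nm = 10) {
  stopifnot(is_spectrum(s))
  if (peak_nm - half_width_nm < min(s$wavelength_nm) ||
      peak_nm + half_width_nm > max(s$wavelength_nm))
    stop_range("band %.0f+/-%.0f nm extends beyond the %.0f-%.0f nm grid",
               peak_nm, half_width_nm, min(s$wavelength_nm), max(s$wavelength_nm))
  keep <- abs(s$wavelength_nm - peak_nm) <= half_width_nm
  mean(s$value[keep])
}

# Objective for the power search: for each concentration level, the squared
# coefficient of variation of corrected peak-band intensity across the
# optical-property combinations, summed over concentrations. Scale-free, so
# the arbitrary overall gain of the corrected spectra cannot game it.
powers_objective <- function(ab, groups, ctxs, peaks) {
  total <- 0
  for (g in groups) {
    vals <- vapply(g, function(i) {
      sc <- ctxs[[i]]$r_ex^ab[1] * ctxs[[i]]$r_em^ab[2]
      peaks[[i]]$raw / sc
    }, numeric(1))
    m <- mean(vals)
    if (m <= 0) return(Inf)
    total <- total + (stats::sd(vals) / m)^2
  }
  total
}

#' Optimize the correction power pair on a fluorescence phantom set
#'
#' Finds (alpha, beta) that make corrected peak-band intensities converge
#' across absorption-scattering combinations sharing a concentration:
#' derivative-free Nelder-Mead simplex from (0, 0) (one restart from the
#' first optimum), minimizing the summed squared coefficient of variation of
#' corrected peak-band intensity across optical-property combos, summed over
#' concentration levels.
#'
#' @param phantom_set output of `make_phantom_set("fluorescence", ...)`.
#' @param channel `"ch1"` or `"ch2"` (powers are system/channel specific).
#' @param emission_peak_nm band center for the peak-band mean; defaults to
#'   the fluorophore's configured peak.
#' @param half_width_nm peak band half width (nm).
#' @param maxit simplex iteration budget.
#' @param reltol simplex relative convergence tolerance.
#' @return A [correction_powers] with the objective value at the optimum.
#' @export
optimize_powers <- function(phantom_set, channel = "ch1",
                            emission_peak_nm = NULL, half_width_nm = 10,
                            maxit = 2000, reltol = 1e-10) {
  man <- phantom_set$manifest
  if (!all(man$design == "fluorescence"))
    stop_validation("optimize_powers needs a fluorescence phantom set")
  fluorophore <- man$fluorophore[1]
  fi <- fluorophore_info(fluorophore)
  if (is.null(emission_peak_nm)) emission_peak_nm <- fi$emission_peak_nm

  ctxs <- lapply(phantom_set$phantoms, function(p)
    correction_context(p$reflectance[[channel]], fluorophore, emission_peak_nm))
  peaks <- lapply(phantom_set$phantoms, function(p)
    list(raw = peak_band_mean(p$fluorescence[[channel]], emission_peak_nm,
                              half_width_nm)))
  groups <- split(seq_len(nrow(man)), man$fluorophore_conc)
  n_combo <- lengths(groups)
  if (any(n_combo < 2))
    stop_domain("need >= 2 optical-property combinations per concentration (objective degenerate)")

  obj <- function(ab) powers_objective(ab, groups, ctxs, peaks)
  o1 <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = reltol))
  o2 <- stats::optim(o1$par, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = reltol))
  best <- if (o2$value <= o1$value) o2 else o1
  # monotone acceptance: never worse than the (0, 0) start
  if (best$value > obj(c(0, 0))) {
    best <- list(par = c(0, 0), value = obj(c(0, 0)), convergence = 1L)
  }
  correction_powers(best$par[1], best$par[2], fluorophore,
                    channel_id = if (channel == "ch1") 1 else 2,
                    objective_value = best$value,
                    converged = best$convergence == 0)
}

#' Benchmark model-divide intrinsic-fluorescence correction
#'
#' Divides the raw emission wavelength-wise by the forward model's
#' attenuation factor (excitation transport weight at the excitation peak
#' times the emission escape weight at each emission wavelength) evaluated
#' at the optical properties recovered by [invert_reflectance]. This is the
#' inversion-based reference the ratio-metric correction is validated
#' against.
#'
#' @param f_raw a fluorescence [spectrum].
#' @param inv an [inversion_result] (must have converged).
#' @param geom the [probe_geometry] of the measurement.
#' @param fluorophore `"NBDG"` or `"TMRE"`; defaults to the spectrum's
#'   metadata.
#' @param model forward kernel name (see [forward_reflectance]).
#' @return The corrected fluorescence [spectrum].
#' @export
model_divide_correction <- function(f_raw, inv, geom, fluorophore = NULL,
                                    model = c("short_sds", "diffusion")) {
  model <- match.arg(model)
  stopifnot(is_spectrum(f_raw), inherits(inv, "inversion_result"))
  if (f_raw$kind != "fluorescence")
    stop_validation("model_divide_correction needs a fluorescence spectrum")
  if (!isTRUE(inv$converged))
    stop_validation("inversion result did not converge; refuse to correct")
  if (is.null(fluorophore)) fluorophore <- f_raw$meta$fluorophore
  if (is.null(fluorophore))
    stop_validation("fluorophore not given and absent from spectrum metadata")
  fi <- fluorophore_info(fluorophore)
  props <- inv$fitted_props
  if (min(props$wavelength_nm) > min(f_raw$wavelength_nm) ||
      max(props$wavelength_nm) < max(f_raw$wavelength_nm))
    stop_range("emission band extends beyond the fitted property grid")
  w_ex <- transport_weight(props, geom, fi$excitation_nm, model)
  w_em <- transport_weight(props, geom, f_raw$wavelength_nm, model)
  atten <- w_ex * w_em
  if (any(atten <= 0)) stop_model("attenuation factor non-positive")
  meta <- f_raw$meta
  meta$corrected <- "model_divide"
  spectrum(f_raw$wavelength_nm, f_raw$value / atten, "fluorescence", meta)
}

#' Write / read a correction-powers file
#'
#' Small delimited text record (fluorophore, channel, alpha, beta,
#' objective, converged).
#'
#' @param powers a [correction_powers].
#' @param path file path.
#' @return `read_correction_powers` returns a [correction_powers].
#' @export
write_correction_powers <- function(powers, path) {
  df <- data.frame(fluorophore = powers$fluorophore,
                   channel_id = powers$channel_id,
                   alpha = powers$alpha, beta = powers$beta,
                   objective = powers$objective_value,
                   converged = powers$converged)
  utils::write.table(format(df, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correction_powers
#' @export
read_correction_powers <- function(path) {
  if (!file.exists(path)) stop_validation("powers file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  correction_powers(as.numeric(df$alpha[1]), as.numeric(df$beta[1]),
                    df$fluorophore[1], as.integer(df$channel_id[1]),
                    as.numeric(df$objective[1]), as.logical(df$converged[1]))
}
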