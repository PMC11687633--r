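# Benchmark estimator: bounded least-squares fit of a measured reflectance
# spectrum with the forward kernel, parameterized directly in
# (c_hb, c_hbo2, scatter amplitude, scatter exponent). Concentrations are
# optimized in micromolar so all four parameters have comparable magnitude.

#' Fit a reflectance spectrum for optical properties and hemoglobin
#'
#' Minimizes the unweighted sum of squared residuals between the measured
#' calibrated reflectance and the forward model over theta = (C_Hb, C_HbO2,
#' scatter amplitude, scatter exponent), all bound-constrained (>= 0;
#' exponent in \[0, 4\]), by Levenberg-Marquardt least squares with a
#' 5-point Latin-hypercube multistart (fixed seed). StO2 and total
#' hemoglobin follow from the recovered concentrations.
#'
#' @param measured a reflectance [spectrum] covering 450-650 nm, positive on
#'   the fit band.
#' @param geom the [probe_geometry] the spectrum was acquired with.
#' @param table an [extinction_table].
#' @param init optional starting point, list/vector
#'   `(c_hb_molar, c_hbo2_molar, scatter_amplitude, scatter_exponent)`.
#' @param n_starts Latin-hypercube multistart size.
#' @param seed seed for the multistart design.
#' @param fit_band wavelength window used for the fit (nm).
#' @param prop_grid grid on which fitted properties are reconstructed.
#' @param model forward kernel name (see [forward_reflectance]); must match
#'   the kernel that generated (or best represents) the measurement.
#' @return An object of class `inversion_result`: `fitted_props`
#'   ([optical_properties]), `c_hb_molar`, `c_hbo2_molar`, `sto2`,
#'   `thb_mg_per_ml`, `sse`, `converged`, `n_iter`, `theta`.
#' @export
invert_reflectance <- function(measured, geom, table = load_extinction(),
                               init = NULL, n_starts = 5, seed = 1L,
                               fit_band = c(450, 650), prop_grid = 400:680,
                               model = c("short_sds", "diffusion")) {
  model <- match.arg(model)
  stopifnot(is_spectrum(measured))
  if (measured$kind != "reflectance")
    stop_validation("invert_reflectance needs a reflectance spectrum, got %s",
                    measured$kind)
  assert_covers(measured, fit_band[1], fit_band[2], "measured")
  fit <- spectrum_window(measured, fit_band[1], fit_band[2])
  if (any(fit$value <= 0))
    stop_domain("reflectance must be positive on the fit band")

  tb <- resample_extinction(table, fit$wavelength_nm)
  rho <- geom$sds_mm / 10
  # theta scaled: concentrations in uM, amplitude cm^-1, exponent unitless
  lower <- c(0, 0, 1, 0)
  upper <- c(300, 300, 60, 4)
  fwd <- function(th) {
    mua <- log(10) * 1e-6 * (th[1] * tb$eps_hb + th[2] * tb$eps_hbo2)
    musp <- musp_power_law(th[3], th[4], fit$wavelength_nm)
    forward_reflectance(mua, musp, rho, model)
  }
  resid_fun <- function(th) fwd(th) - fit$value
  sse_of <- function(th) sum(resid_fun(th)^2)

  # data-driven start: solve the scatter amplitude from the red end of the
  # spectrum (weak hemoglobin absorption), assuming exponent 1
  red <- fit$wavelength_nm >= 630
  r_red <- mean(fit$value[red]); wl_red <- mean(fit$wavelength_nm[red])
  amp0 <- tryCatch(stats::uniroot(function(a)
    forward_reflectance(0.2, a * (wl_red / 550)^(-1), rho, model) - r_red,
    c(lower[3], upper[3]))$root, error = function(e) 15)
  starts <- list(c(20, 60, amp0, 1))
  if (!is.null(init)) {
    init <- as.numeric(unlist(init))
    starts <- list(c(init[1] * 1e6, init[2] * 1e6, init[3], init[4]))
  }
  if (n_starts > 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(as.integer(seed))
    u <- lhs::randomLHS(n_starts - 1, 4)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    for (k in seq_len(nrow(u)))
      starts[[k + 1]] <- lower + u[k, ] * (upper - lower)
  }

  best <- NULL
  for (st in starts) {
    f0 <- try(minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500)), silent = TRUE)
    if (inherits(f0, "try-error")) next
    cand <- list(theta = as.numeric(f0$par), sse = f0$deviance,
                 n_iter = f0$niter, converged = f0$info %in% 1:4)
    take <- is.null(best) || cand$sse < best$sse ||
      (isTRUE(all.equal(cand$sse, best$sse)) &&
         sum(cand$theta[1:2]) < sum(best$theta[1:2]))  # parsimony tie-break
    if (take) best <- cand
  }
  if (is.null(best)) {
    th0 <- starts[[1]]
    best <- list(theta = th0, sse = sse_of(th0), n_iter = 0L, converged = FALSE)
  }
  # descent contract: never return a point worse than the first start
  if (best$sse > sse_of(starts[[1]])) {
    best <- list(theta = starts[[1]], sse = sse_of(starts[[1]]),
                 n_iter = best$n_iter, converged = FALSE)
  }

  th <- best$theta
  c_hb <- th[1] * 1e-6
  c_hbo2 <- th[2] * 1e-6
  thb <- (c_hb + c_hbo2) * 64500
  sto2 <- if (c_hb + c_hbo2 > 0) c_hbo2 / (c_hb + c_hbo2) else NA_real_
  tb_full <- resample_extinction(table, prop_grid)
  props <- optical_properties(
    prop_grid,
    log(10) * (c_hb * tb_full$eps_hb + c_hbo2 * tb_full$eps_hbo2),
    musp_power_law(th[3], th[4], prop_grid))
  structure(list(fitted_props = props, c_hb_molar = c_hb,
                 c_hbo2_molar = c_hbo2, sto2 = sto2, thb_mg_per_ml = thb,
                 sse = best$sse, converged = best$converged,
                 n_iter = best$n_iter,
                 theta = c(c_hb_molar = c_hb, c_hbo2_molar = c_hbo2,
                           scatter_amplitude = th[3], scatter_exponent = th[4]),
                 channel = geom$channel_id),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("<inversion_result: StO2 %.3f, [THB] %.2f mg/mL, SSE %.3g, %s after %d iter>\n",
              x$sto2, x$thb_mg_per_ml, x$sse,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Unmix an absorption spectrum into hemoglobin components
#'
#' Nonnegative least squares of mu_a(lambda) on \[ln(10) eps_Hb,
#' ln(10) eps_HbO2\] over a wavelength band; StO2 is the oxy fraction of the
#' recovered concentrations.
#'
#' @param wavelength_nm wavelengths of `mua` (nm).
#' @param mua absorption spectrum (cm^-1); small negative noise excursions
#'   are tolerated (NNLS keeps the solution nonnegative).
#' @param table an [extinction_table].
#' @param band fit window `c(lo, hi)` nm.
#' @param molar_mass_g_per_mol hemoglobin molar mass for the mg/mL report.
#' @return list with `c_hb`, `c_hbo2` (mol/L), `sto2` (NA with
#'   `sto2_defined = FALSE` when both components are zero), `thb_mg_per_ml`.
#' @export
unmix_mua <- function(wavelength_nm, mua, table = load_extinction(),
                      band = c(450, 650), molar_mass_g_per_mol = 64500) {
  keep <- wavelength_nm >= band[1] & wavelength_nm <= band[2]
  if (sum(keep) < 2) stop_validation("unmixing needs >= 2 wavelengths in band")
  tb <- resample_extinction(table, wavelength_nm[keep])
  A <- cbind(log(10) * tb$eps_hb, log(10) * tb$eps_hbo2)
  sol <- pracma::lsqnonneg(A, as.numeric(mua[keep]))
  c_hb <- sol$x[1]; c_hbo2 <- sol$x[2]
  tot <- c_hb + c_hbo2
  list(c_hb = c_hb, c_hbo2 = c_hbo2,
       sto2 = if (tot > 0) c_hbo2 / tot else NA_real_,
       sto2_defined = tot > 0,
       thb_mg_per_ml = tot * molar_mass_g_per_mol)
}
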