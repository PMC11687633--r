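# Time-resolved corrected fluorescence and the derived metabolic endpoints:
# delivery rate RD = peak / time-to-peak, delivery-corrected uptake
# (NBDG60/RD), and the 80-min mitochondrial-probe snapshot (TMRE80).

#' Kinetic uptake trace
#'
#' Corrected peak-band fluorescence intensity over time, on the probe's own
#' post-injection clock. The injection offset records where the probe's
#' clock sits on the experiment clock: 0 min for the mitochondrial probe,
#' 20 min for the glucose analog (injected with a 20-min delay).
#'
#' @param time_min times relative to that probe's injection (min), strictly
#'   increasing (pre-injection samples are negative).
#' @param intensity corrected peak-band intensities, finite and >= 0.
#' @param fluorophore `"NBDG"` or `"TMRE"`.
#' @param injection_offset_min override of the default offset.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time_min, intensity,
                          fluorophore = c("NBDG", "TMRE"),
                          injection_offset_min = NULL) {
  fluorophore <- match.arg(fluorophore)
  if (length(time_min) != length(intensity))
    stop_validation("time and intensity lengths differ")
  if (any(diff(time_min) <= 0))
    stop_validation("times must be strictly increasing (duplicates/unsorted)")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop_validation("intensities must be finite and >= 0")
  if (is.null(injection_offset_min))
    injection_offset_min <- if (fluorophore == "NBDG") 20 else 0
  structure(list(time_min = as.numeric(time_min),
                 intensity = as.numeric(intensity),
                 fluorophore = fluorophore,
                 injection_offset_min = injection_offset_min),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace: %s, %d samples, %.0f-%.0f min post-injection>\n",
              x$fluorophore, length(x$time_min), min(x$time_min),
              max(x$time_min)))
  invisible(x)
}

#' Build a kinetic trace from time-stamped spectra
#'
#' Per time point: optionally subtract the pre-injection baseline spectrum
#' (point-wise, in spectrum space), apply the ratio-metric correction using
#' that time point's paired reflectance, then take the emission peak-band
#' mean. Times are sorted into the trace.
#'
#' @param fluor_spectra list of fluorescence [spectrum] objects, each with
#'   `meta$time_min` (experiment clock).
#' @param refl_spectra list of paired reflectance [spectrum] objects (same
#'   order/length).
#' @param powers a [correction_powers] for this fluorophore/channel.
#' @param emission_peak_nm band center; defaults to the fluorophore's peak.
#' @param half_width_nm band half width (nm).
#' @param baseline optional pre-injection fluorescence [spectrum] to
#'   subtract (negative differences floor at 0).
#' @return A [kinetic_trace] (times converted to post-injection clock).
#' @export
build_trace <- function(fluor_spectra, refl_spectra, powers,
                        emission_peak_nm = NULL, half_width_nm = 10,
                        baseline = NULL) {
  if (length(fluor_spectra) < 3)
    stop_validation("a kinetic trace needs >= 3 time points")
  if (length(refl_spectra) != length(fluor_spectra))
    stop_validation("every fluorescence spectrum needs a paired reflectance")
  fluorophore <- powers$fluorophore
  fi <- fluorophore_info(fluorophore)
  if (is.null(emission_peak_nm)) emission_peak_nm <- fi$emission_peak_nm
  times <- vapply(fluor_spectra, function(s) {
    tm <- s$meta$time_min
    if (is.null(tm)) stop_validation("fluorescence spectrum lacks meta$time_min")
    as.numeric(tm)
  }, numeric(1))
  if (anyDuplicated(times))
    stop_validation("duplicate timestamps in the kinetic series")
  ord <- order(times)
  vals <- vapply(ord, function(i) {
    f <- fluor_spectra[[i]]
    if (!is.null(baseline)) {
      if (!isTRUE(all.equal(baseline$wavelength_nm, f$wavelength_nm)))
        stop_validation("baseline grid does not match the fluorescence grid")
      f <- spectrum(f$wavelength_nm, pmax(0, f$value - baseline$value),
                    "fluorescence", f$meta)
    }
    ctx <- correction_context(refl_spectra[[i]], fluorophore, emission_peak_nm)
    fc <- correct_fluorescence(f, ctx, powers)
    peak_band_mean(fc, emission_peak_nm, half_width_nm)
  }, numeric(1))
  t0 <- if (fluorophore == "NBDG") 20 else 0
  kinetic_trace(times[ord] - t0, vals, fluorophore)
}

#' Delivery rate of a glucose-analog trace
#'
#' RD = peak intensity / time of first maximum, the vascular-delivery
#' normalizer for uptake endpoints.
#'
#' @param trace a [kinetic_trace].
#' @return list with `rd`, `peak`, `time_peak_min`.
#' @export
delivery_rate <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  post <- trace$time_min >= 0
  tt <- trace$time_min[post]; ii <- trace$intensity[post]
  pk <- max(ii)
  # first time attaining the maximum; ties at t = 0 defer to later samples
  at_pk <- which(ii >= pk * (1 - 1e-12))
  at_pk <- at_pk[tt[at_pk] > 0]
  if (!length(at_pk))
    stop_domain("trace peaks at injection time; delivery rate undefined")
  i_pk <- at_pk[1]
  list(rd = ii[i_pk] / tt[i_pk], peak = ii[i_pk], time_peak_min = tt[i_pk])
}

# Sample nearest a target post-injection time, within +/- tol.
intensity_near <- function(trace, t_min, tol_min = 2) {
  i <- which.min(abs(trace$time_min - t_min))
  if (abs(trace$time_min[i] - t_min) > tol_min)
    stop_range("%s trace has no sample within %.0f min of t = %.0f min",
               trace$fluorophore, tol_min, t_min)
  trace$intensity[i]
}

#' Metabolic endpoint summary of a paired probe session
#'
#' NBDG60 (glucose-analog intensity nearest 60 min post its injection),
#' TMRE80 (mitochondrial-probe intensity nearest 80 min post its injection),
#' the delivery rate RD, and the delivery-corrected uptake NBDG60/RD.
#' Because of the 20-min injection delay, the two endpoint snapshots fall on
#' the same experiment-clock instant (80 min) - asserted here.
#'
#' @param nbdg_trace,tmre_trace [kinetic_trace] objects spanning >= 60 and
#'   >= 80 min post-injection respectively.
#' @param tol_min nearest-sample tolerance (min).
#' @return list of class `metabolic_endpoints`: `nbdg_peak`,
#'   `time_peak_min`, `rd`, `nbdg60`, `nbdg60_over_rd`, `tmre80`.
#' @export
endpoint_summary <- function(nbdg_trace, tmre_trace, tol_min = 2) {
  stopifnot(inherits(nbdg_trace, "kinetic_trace"),
            inherits(tmre_trace, "kinetic_trace"))
  if (nbdg_trace$fluorophore != "NBDG" || tmre_trace$fluorophore != "TMRE")
    stop_validation("traces must be (NBDG, TMRE) in that order")
  clock_nbdg <- nbdg_trace$injection_offset_min + 60
  clock_tmre <- tmre_trace$injection_offset_min + 80
  if (clock_nbdg != clock_tmre)
    stop_validation("endpoint snapshots misaligned: NBDG60 at clock %.0f vs TMRE80 at clock %.0f min",
                    clock_nbdg, clock_tmre)
  if (max(nbdg_trace$time_min) < 60 - tol_min)
    stop_range("NBDG trace must span >= 60 min post-injection")
  if (max(tmre_trace$time_min) < 80 - tol_min)
    stop_range("TMRE trace must span >= 80 min post-injection")
  dr <- delivery_rate(nbdg_trace)
  nbdg60 <- intensity_near(nbdg_trace, 60, tol_min)
  tmre80 <- intensity_near(tmre_trace, 80, tol_min)
  structure(list(nbdg_peak = dr$peak, time_peak_min = dr$time_peak_min,
                 rd = dr$rd, nbdg60 = nbdg60,
                 nbdg60_over_rd = nbdg60 / dr$rd, tmre80 = tmre80),
            class = "metabolic_endpoints")
}

#' @export
print.metabolic_endpoints <- function(x, ...) {
  cat(sprintf("<metabolic_endpoints: RD %.4g (peak %.4g @ %.1f min), NBDG60/RD %.4g, TMRE80 %.4g>\n",
              x$rd, x$nbdg_peak, x$time_peak_min, x$nbdg60_over_rd, x$tmre80))
  invisible(x)
}

#' Two-group comparison and correlation reporting utilities
#'
#' Thin wrappers over [stats::t.test] (Welch unequal-variance by default;
#' set `var_equal = TRUE` for the pooled test) and [stats::cor.test]
#' (Pearson), for endpoint group contrasts.
#'
#' @param values_a,values_b numeric endpoint vectors (>= 2 each).
#' @param var_equal pooled-variance t-test if TRUE.
#' @return `compare_groups`: list with `t`, `p`; `correlate`: list with
#'   `r`, `p`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_validation("each group needs >= 2 values")
  if (stats::sd(c(values_a, values_b)) == 0)
    return(list(t = 0, p = 1))
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' @param x,y paired numeric vectors (>= 3 pairs) for `correlate`.
#' @rdname compare_groups
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_validation("correlation needs >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_validation("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
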