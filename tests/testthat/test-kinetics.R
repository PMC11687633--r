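# Kinetic traces and metabolic endpoints.

# time-stamped spectrum series for build_trace tests
make_series <- function(fluorophore = "NBDG", amplitude = 5, k_in = 0.15,
                        k_out = 0.01, clock_times = seq(0, 80, by = 4),
                        thb = 2, so2 = 0.8) {
  props <- sim_props(thb = thb, so2 = so2)
  geom <- probe_geometry(1)
  refl <- simulate_reflectance(props, geom)
  t0 <- if (fluorophore == "NBDG") 20 else 0
  tt <- pmax(0, clock_times - t0)
  model <- amplitude * (1 - exp(-k_in * tt)) * exp(-k_out * tt)
  fs <- lapply(seq_along(clock_times), function(i) {
    f <- simulate_fluorescence(props, fluorophore, 1, geom)
    s <- spectrum(f$wavelength_nm, model[i] * f$value, "fluorescence", f$meta)
    s$meta$time_min <- clock_times[i]
    s
  })
  list(fluor = fs, refl = rep(list(refl), length(clock_times)), model = model,
       clock_times = clock_times)
}

test_that("build_trace corrects, band-averages, and sorts", {
  ser <- make_series("NBDG")
  pw <- correction_powers(1, 1, "NBDG")
  tr <- build_trace(ser$fluor, ser$refl, pw)
  expect_s3_class(tr, "kinetic_trace")
  expect_equal(tr$time_min, ser$clock_times - 20)
  # noiseless series: trace proportional to the generating model
  pos <- ser$model > 0
  ratio <- tr$intensity[pos] / ser$model[pos]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  # shuffled input order comes back time-sorted
  idx <- sample(seq_along(ser$fluor))
  tr2 <- build_trace(ser$fluor[idx], ser$refl[idx], pw)
  expect_identical(tr2$time_min, tr$time_min)
  expect_identical(tr2$intensity, tr$intensity)
})

test_that("null powers reproduce raw peak-band means and zero input stays zero", {
  ser <- make_series("TMRE")
  p0 <- correction_powers(0, 0, "TMRE")
  tr <- build_trace(ser$fluor, ser$refl, p0)
  raw <- vapply(ser$fluor, function(s) peak_band_mean(s, 580), numeric(1))
  expect_equal(tr$intensity, raw[order(ser$clock_times)])
  zero <- lapply(ser$fluor, function(s)
    spectrum(s$wavelength_nm, rep(0, length(s$value)), "fluorescence", s$meta))
  expect_true(all(build_trace(zero, ser$refl, p0)$intensity == 0))
})

test_that("baseline spectra are subtracted before correction", {
  ser <- make_series("TMRE")
  base <- spectrum(ser$fluor[[1]]$wavelength_nm,
                   rep(0.001, length(ser$fluor[[1]]$value)), "fluorescence")
  shifted <- lapply(ser$fluor, function(s)
    spectrum(s$wavelength_nm, s$value + 0.001, "fluorescence", s$meta))
  pw <- correction_powers(0.5, 0.5, "TMRE")
  tr_ref <- build_trace(ser$fluor, ser$refl, pw)
  tr_sub <- build_trace(shifted, ser$refl, pw, baseline = base)
  expect_equal(tr_sub$intensity, tr_ref$intensity, tolerance = 1e-10)
  # a constant offset leaves the peak time unchanged
  expect_equal(delivery_rate(tr_sub)$time_peak_min,
               delivery_rate(tr_ref)$time_peak_min)
})

test_that("build_trace validates its inputs", {
  ser <- make_series("NBDG")
  pw <- correction_powers(0, 0, "NBDG")
  expect_error(build_trace(ser$fluor[1:2], ser$refl[1:2], pw),
               class = "ts_validation_error")
  expect_error(build_trace(ser$fluor, ser$refl[-1], pw),
               class = "ts_validation_error")
  dup <- ser$fluor
  dup[[2]]$meta$time_min <- dup[[1]]$meta$time_min
  expect_error(build_trace(dup, ser$refl, pw), class = "ts_validation_error")
})

test_that("delivery rate is peak over first-maximum time", {
  tr <- kinetic_trace(c(1, 5, 10, 20), c(4, 10, 8, 6), "NBDG")
  dr <- delivery_rate(tr)
  expect_equal(dr$rd, 2.0)            # 10 / 5
  expect_equal(dr$time_peak_min, 5)
  # monotone saturating trace peaks at the boundary
  sat <- simulate_kinetic_trace("NBDG", 5, 0.1, 0,
                                times_min = seq(20, 80, by = 2))
  dr2 <- delivery_rate(sat)
  expect_equal(dr2$time_peak_min, 60)
  expect_equal(dr2$rd, max(sat$intensity) / 60)
  # two-rate trace: peak within one sampling step of the closed form
  tr3 <- simulate_kinetic_trace("TMRE", 5, 0.15, 0.01,
                                times_min = seq(0, 80, by = 2))
  expect_lt(abs(delivery_rate(tr3)$time_peak_min -
                  kinetic_peak_time(0.15, 0.01)), 2 + 1e-9)
  # peak at injection time is undefined
  dec <- kinetic_trace(c(0, 5, 10), c(10, 8, 6), "NBDG")
  expect_error(delivery_rate(dec), class = "ts_domain_error")
})

test_that("endpoint snapshots align on the experiment clock", {
  nb <- simulate_kinetic_trace("NBDG", 5, 0.15, 0.01,
                               times_min = seq(0, 80, by = 2))
  tm <- simulate_kinetic_trace("TMRE", 3, 0.2, 0.005,
                               times_min = seq(0, 80, by = 2))
  ep <- endpoint_summary(nb, tm)
  expect_s3_class(ep, "metabolic_endpoints")
  expect_equal(ep$nbdg60, nb$intensity[nb$time_min == 60])
  expect_equal(ep$tmre80, tm$intensity[tm$time_min == 80])
  expect_equal(ep$nbdg60_over_rd, ep$nbdg60 / ep$rd)
  # misaligned offsets are refused
  nb_bad <- nb; nb_bad$injection_offset_min <- 10
  expect_error(endpoint_summary(nb_bad, tm), class = "ts_validation_error")
  # insufficient span
  short <- simulate_kinetic_trace("TMRE", 3, 0.2, 0.005,
                                  times_min = seq(0, 60, by = 2))
  expect_error(endpoint_summary(nb, short), class = "ts_range_error")
})

test_that("delivery-corrected uptake is scale invariant", {
  nb <- simulate_kinetic_trace("NBDG", 5, 0.15, 0.01,
                               times_min = seq(0, 80, by = 2))
  tm <- simulate_kinetic_trace("TMRE", 3, 0.2, 0.005,
                               times_min = seq(0, 80, by = 2))
  nb_scaled <- kinetic_trace(nb$time_min, 11 * nb$intensity, "NBDG")
  ep <- endpoint_summary(nb, tm)
  ep_s <- endpoint_summary(nb_scaled, tm)
  expect_equal(ep_s$nbdg60_over_rd, ep$nbdg60_over_rd, tolerance = 1e-12)
  # constant trace: intensity cancels, leaving the first positive sample time
  const <- kinetic_trace(seq(2, 62, 2), rep(4, 31), "NBDG")
  expect_equal(endpoint_summary(const, tm)$nbdg60_over_rd, 2)
})

test_that("endpoints are stable under finer sampling of a noiseless trace", {
  coarse <- simulate_kinetic_trace("NBDG", 5, 0.15, 0.01,
                                   times_min = seq(0, 80, by = 4))
  fine <- simulate_kinetic_trace("NBDG", 5, 0.15, 0.01,
                                 times_min = seq(0, 80, by = 0.5))
  tm <- simulate_kinetic_trace("TMRE", 3, 0.2, 0.005,
                               times_min = seq(0, 80, by = 2))
  ep_c <- endpoint_summary(coarse, tm)
  ep_f <- endpoint_summary(fine, tm)
  expect_lt(abs(ep_c$time_peak_min - ep_f$time_peak_min), 4 + 1e-9)
  expect_equal(ep_c$nbdg60, ep_f$nbdg60, tolerance = 0.02)
})

test_that("cohorts with shifted uptake rates order as constructed", {
  tm <- simulate_kinetic_trace("TMRE", 3, 0.2, 0.005,
                               times_min = seq(0, 80, by = 2))
  cohort <- function(k_in_base, seed) vapply(1:7, function(i) {
    nb <- simulate_kinetic_trace("NBDG", 5, k_in_base + 0.005 * i, 0.01,
                                 times_min = seq(0, 80, by = 2),
                                 noise_sd_frac = 0.01, seed = seed + i)
    endpoint_summary(nb, tm)$nbdg60_over_rd
  }, numeric(1))
  slow <- cohort(0.05, 100)   # slower delivery: longer time-to-peak
  fast <- cohort(0.25, 200)
  expect_gt(mean(slow), mean(fast))
  cg <- compare_groups(slow, fast)
  expect_lt(cg$p, 0.05)
})

test_that("group comparison and correlation report the standard statistics", {
  g <- c(1, 2, 3, 4)
  same <- compare_groups(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compare_groups(1, c(1, 2)), class = "ts_validation_error")
  expect_equal(correlate(c(1, 2, 3), c(2, 4, 6))$r, 1, tolerance = 1e-12)
  x <- c(1, 2, 3, 5, 8)
  expect_equal(correlate(x, x)$r, 1, tolerance = 1e-12)
  expect_error(correlate(c(1, 2), c(1, 2)), class = "ts_validation_error")
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), class = "ts_validation_error")
})
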