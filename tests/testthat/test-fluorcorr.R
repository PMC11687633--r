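# Ratio-metric fluorescence correction, power optimization, and the
# model-divide benchmark.

make_fluor_set <- function(fluorophore = "TMRE", noise = 0, seed = 3) {
  make_phantom_set("fluorescence", seed = seed, fluorophore = fluorophore,
                   noise_sd_frac = noise)
}

test_that("the correction formula is the stated closed form", {
  f <- simulate_fluorescence(sim_props(), "TMRE", 60, probe_geometry(1))
  r <- sim_refl()
  ctx <- correction_context(r, "TMRE")
  # null powers leave the spectrum untouched
  p0 <- correction_powers(0, 0, "TMRE")
  expect_equal(correct_fluorescence(f, ctx, p0)$value, f$value)
  # alpha = 1, beta = 0 divides by r_ex; with r_ex = 0.5 every value doubles
  ctx2 <- ctx; ctx2$r_ex <- 0.5
  expect_equal(correct_fluorescence(f, ctx2, correction_powers(1, 0, "TMRE"))$value,
               2 * f$value)
  # homogeneity: correcting k * F equals k * corrected F
  fk <- spectrum(f$wavelength_nm, 3.7 * f$value, "fluorescence", f$meta)
  pw <- correction_powers(0.8, -0.3, "TMRE")
  expect_equal(correct_fluorescence(fk, ctx, pw)$value,
               3.7 * correct_fluorescence(f, ctx, pw)$value, tolerance = 1e-12)
})

test_that("peak band mean averages the +/- 10 nm band inclusively", {
  grid <- 520:600
  const <- spectrum(grid, rep(3, length(grid)), "fluorescence")
  expect_equal(peak_band_mean(const, 545), 3)
  expect_equal(peak_band_mean(const, 545, half_width_nm = 4), 3)
  # symmetric triangular peak: mean over the sampled band computed directly
  tri <- pmax(0, 10 - abs(grid - 560))
  s_tri <- spectrum(grid, tri, "fluorescence")
  keep <- abs(grid - 560) <= 10
  expect_equal(peak_band_mean(s_tri, 560), mean(tri[keep]))
  # band beyond the grid edge errors
  expect_error(peak_band_mean(s_tri, 595), class = "ts_range_error")
})

test_that("optimized powers strictly improve convergence across optical properties", {
  for (fl in c("TMRE", "NBDG")) {
    fs <- make_fluor_set(fl)
    pw <- optimize_powers(fs, "ch1")
    fi <- fluorophore_info(fl)
    ctxs <- lapply(fs$phantoms, function(p) correction_context(p$reflectance$ch1, fl))
    peaks <- lapply(fs$phantoms, function(p)
      list(raw = peak_band_mean(p$fluorescence$ch1, fi$emission_peak_nm)))
    groups <- split(seq_len(nrow(fs$manifest)), fs$manifest$fluorophore_conc)
    obj0 <- tissuespec:::powers_objective(c(0, 0), groups, ctxs, peaks)
    expect_lt(pw$objective_value, obj0)
    expect_true(pw$converged)
  }
})

test_that("powers are per-channel and the objective refuses a single combination", {
  fs <- make_fluor_set("TMRE")
  pw1 <- optimize_powers(fs, "ch1")
  pw2 <- optimize_powers(fs, "ch2")
  expect_equal(pw1$channel_id, 1)
  expect_equal(pw2$channel_id, 2)
  # cut the set down to one optical-property combination per concentration
  keep <- fs$manifest$scatter_amplitude == fs$manifest$scatter_amplitude[1] &
    fs$manifest$thb_mg_per_ml == fs$manifest$thb_mg_per_ml[1]
  degenerate <- list(phantoms = fs$phantoms[keep],
                     manifest = fs$manifest[keep, ])
  expect_error(optimize_powers(degenerate, "ch1"), class = "ts_domain_error")
})

test_that("with no attenuation there is nothing to correct", {
  # build spectra by hand: emission = conc x lineshape, reflectance flat
  grid <- 400:680
  flat_refl <- spectrum(grid, rep(0.25, length(grid)), "reflectance")
  emg <- 565:650
  shape <- tissuespec:::fluor_lineshape("TMRE", emg)
  phantoms <- list(); rows <- list()
  i <- 0
  for (conc in c(30, 60, 90)) for (combo in 1:2) {
    i <- i + 1
    phantoms[[i]] <- list(
      reflectance = list(ch1 = flat_refl),
      fluorescence = list(ch1 = spectrum(emg, conc * shape, "fluorescence")))
    rows[[i]] <- data.frame(design = "fluorescence", fluorophore = "TMRE",
                            fluorophore_conc = conc)
  }
  fs <- list(phantoms = phantoms, manifest = do.call(rbind, rows))
  pw <- optimize_powers(fs, "ch1")
  expect_lte(pw$objective_value, 1e-16)
})

test_that("the optimized correction restores concentration linearity", {
  for (fl in c("TMRE", "NBDG")) {
    fs <- make_fluor_set(fl)           # noiseless
    pw <- optimize_powers(fs, "ch1")
    fi <- fluorophore_info(fl)
    corr <- vapply(fs$phantoms, function(p) {
      ctx <- correction_context(p$reflectance$ch1, fl)
      peak_band_mean(correct_fluorescence(p$fluorescence$ch1, ctx, pw),
                     fi$emission_peak_nm)
    }, numeric(1))
    conc <- fs$manifest$fluorophore_conc
    # per optical-property combo, corrected intensity is linear through ~0
    combo <- interaction(fs$manifest$thb_mg_per_ml, fs$manifest$scatter_amplitude)
    r2_of <- function(y, x) {
      fit <- stats::lm.fit(cbind(1, x), y)
      1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    }
    for (g in split(seq_along(corr), combo))
      expect_gte(r2_of(corr[g], conc[g]), 0.999)
    # equal-concentration gap between extreme absorptions shrinks vs raw
    man <- fs$manifest
    pick <- function(mua_target) which(
      abs(man$mean_mua_400_600 - mua_target) < 0.1 &
        man$scatter_amplitude == min(man$scatter_amplitude) &
        man$fluorophore_conc == max(man$fluorophore_conc))
    raw <- vapply(fs$phantoms, function(p)
      peak_band_mean(p$fluorescence$ch1, fi$emission_peak_nm), numeric(1))
    gap <- function(v) abs(v[pick(1.5)] - v[pick(4.5)]) / v[pick(1.5)]
    expect_lt(gap(corr), gap(raw))
  }
})

test_that("model-divide correction is exact under self-consistent inversion", {
  fs <- make_fluor_set("TMRE")
  geom <- probe_geometry(1)
  md <- vapply(fs$phantoms, function(p) {
    inv <- invert_reflectance(p$reflectance$ch1, geom, ts_tab)
    peak_band_mean(model_divide_correction(p$fluorescence$ch1, inv, geom, "TMRE"),
                   fluorophore_info("TMRE")$emission_peak_nm)
  }, numeric(1))
  conc <- fs$manifest$fluorophore_conc
  fit <- summary(stats::lm(md ~ conc))
  expect_gte(fit$r.squared, 0.9999)
})

test_that("model-divide responds monotonically to absorption misestimation", {
  props <- sim_props(thb = thb_for_band_mean_mua(3, 1, ts_tab))
  geom <- probe_geometry(1)
  f <- simulate_fluorescence(props, "TMRE", 60, geom)
  r <- simulate_reflectance(props, geom)
  inv <- invert_reflectance(r, geom, ts_tab)
  scale_mua <- function(inv, k) {
    out <- inv
    out$fitted_props <- optical_properties(inv$fitted_props$wavelength_nm,
                                           k * inv$fitted_props$mua,
                                           inv$fitted_props$musp)
    out
  }
  pk <- vapply(c(0.5, 1, 2), function(k)
    peak_band_mean(model_divide_correction(f, scale_mua(inv, k), geom, "TMRE"),
                   580), numeric(1))
  expect_true(all(diff(pk) > 0))  # more assumed absorption, more boost
})

test_that("ratio and model-divide corrections rank phantoms identically", {
  fs <- make_fluor_set("NBDG")
  geom <- probe_geometry(1)
  pw <- optimize_powers(fs, "ch1")
  fi <- fluorophore_info("NBDG")
  both <- vapply(fs$phantoms, function(p) {
    ctx <- correction_context(p$reflectance$ch1, "NBDG")
    inv <- invert_reflectance(p$reflectance$ch1, geom, ts_tab)
    c(ratio = peak_band_mean(correct_fluorescence(p$fluorescence$ch1, ctx, pw),
                             fi$emission_peak_nm),
      md = peak_band_mean(model_divide_correction(p$fluorescence$ch1, inv,
                                                  geom, "NBDG"),
                          fi$emission_peak_nm))
  }, numeric(2))
  # both corrections must reveal the same concentration structure; exact
  # rank order can swap within residual-level ties at equal concentration
  conc <- fs$manifest$fluorophore_conc
  m_ratio <- tapply(both["ratio", ], conc, mean)
  m_md <- tapply(both["md", ], conc, mean)
  expect_identical(order(m_ratio), order(m_md))
  # and each corrected value must sit with its own concentration group:
  # the largest within-group spread stays below the between-group separation
  spread <- function(v) max(tapply(v, conc, function(x) diff(range(x))))
  gapmin <- function(v) min(diff(sort(tapply(v, conc, mean))))
  expect_lt(spread(both["ratio", ]), gapmin(both["ratio", ]))
  expect_lt(spread(both["md", ]), gapmin(both["md", ]))
})

test_that("powers files round trip", {
  pw <- correction_powers(1.23, -0.45, "NBDG", 2, 0.001, TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_correction_powers(pw, path)
  back <- read_correction_powers(path)
  expect_equal(back$alpha, 1.23, tolerance = 1e-12)
  expect_equal(back$beta, -0.45, tolerance = 1e-12)
  expect_equal(back$fluorophore, "NBDG")
  expect_equal(back$channel_id, 2L)
  expect_true(back$converged)
})
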