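# Shared fixtures: the bundled extinction table (read once) and small
# builders for simulated spectra used across test files.

ts_tab <- load_extinction()

# noiseless calibrated reflectance of a homogeneous sample
sim_refl <- function(thb = 3.6, so2 = 1, musp_level = 10, exponent = 1,
                     channel = 1, grid = 400:680) {
  amp <- musp_amplitude_for_band_mean(musp_level, exponent)
  props <- phantom_properties(
    phantom_spec(hemoglobin_state(thb, so2), amp, exponent, noise_sd_frac = 0),
    ts_tab, grid)
  simulate_reflectance(props, probe_geometry(channel))
}

sim_props <- function(thb = 3.6, so2 = 1, musp_level = 10, exponent = 1,
                      grid = 400:680) {
  amp <- musp_amplitude_for_band_mean(musp_level, exponent)
  phantom_properties(
    phantom_spec(hemoglobin_state(thb, so2), amp, exponent, noise_sd_frac = 0),
    ts_tab, grid)
}
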