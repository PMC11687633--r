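# tissuespec

Algorithms for quantitative diffuse reflectance and fluorescence spectroscopy
of biological tissue, aimed at vascular and metabolic phenotyping with
fiber-probe instruments: hemoglobin oxygen saturation (StO2) and total
hemoglobin concentration ([THB]) from calibrated diffuse reflectance, and
intrinsic fluorescence of metabolic probes — a glucose-uptake analog
("NBDG", 2-[N-(7-nitrobenz-2-oxa-1,3-diazol-4-yl)amino]-2-deoxy-D-glucose
class) and a mitochondrial-membrane-potential probe ("TMRE",
tetramethylrhodamine ethyl ester class) — with probe-uptake kinetic
endpoints. A tissue-mimicking phantom simulator is part of the package, so
every estimator is verifiable by round-trip parameter recovery without any
instrument data.

It is written for biomedical-optics researchers who process spectra from
two-channel reflectance/fluorescence fiber probes (source–detector
separations 1.5 mm and 3.0 mm here) and want both the fast analytic
estimators and a model-based inversion benchmark in one place.

## The estimators

**Corrected absorbance and two-wavelength StO2.** From a calibrated
reflectance spectrum R(λ),

    A(λ) = log10(1/R(λ)) − (a + m·λ)

where (a, m) is the least-squares line of log10(1/R) over the
hemoglobin-free scattering band 620–680 nm. A(λ) at the wavelength pair
(555, 575) nm is solved against the oxy/deoxy hemoglobin extinction
coefficients,

    A(λi) = εHb(λi)·xHb + εHbO2(λi)·xHbO2,   x = C·⟨L⟩,

and the unknown mean path length ⟨L⟩ cancels in
StO2 = xHbO2 / (xHb + xHbO2). Negative components are clamped to zero and
flagged.

**Isosbestic ratio for [THB].** R(584)/R(545) — both wavelengths sit at
near-isosbestic crossings of the extinction table, so the ratio tracks total
hemoglobin while being nearly insensitive to saturation. A linear (or
quadratic) calibration against phantoms of known [THB] converts the ratio to
mg/mL.

**Reflectance inversion (benchmark).** Bounded Levenberg–Marquardt least
squares fits the measured spectrum with a semi-infinite forward kernel over
θ = (C_Hb, C_HbO2, scatter amplitude, scatter power), giving μa(λ), μs′(λ),
StO2 and [THB].

**Ratio-metric fluorescence correction.** Raw probe emission is distorted by
tissue absorption and scattering; the correction

    Fcorr(λ) = Fraw(λ) / ([Rex]^α · [Rem]^β)

divides by powers of the reflectance at the excitation and emission peaks.
The system-dependent pair (α, β) is found by Nelder–Mead search on a
fluorescence phantom grid so that corrected intensities converge across
absorption–scattering combinations at equal fluorophore concentration. The
benchmark alternative divides by the forward model's attenuation factor at
inverted optical properties (`model_divide_correction`).

**Uptake kinetics.** Corrected peak-band (emission peak ±10 nm) intensities
over time give the delivery rate RD = peak/time-to-peak, the
delivery-corrected uptake NBDG60/RD (glucose analog at 60 min
post-injection), and TMRE80 (mitochondrial probe at 80 min post-injection);
with the 20-min injection delay both snapshots fall on the same
experiment-clock instant.

## Worked example

```r
library(tissuespec)

tab <- load_extinction()                      # bundled synthetic Hb table

# simulate a phantom measurement: 3.6 mg/mL hemoglobin, 80% oxygenated,
# band-mean scattering 10 cm^-1, channel 1, 1% multiplicative noise
amp   <- musp_amplitude_for_band_mean(10, exponent = 1)
spec  <- phantom_spec(hemoglobin_state(3.6, 0.8), amp, 1)
props <- phantom_properties(spec, tab)
r     <- add_noise(simulate_reflectance(props, probe_geometry(1)), 0.01, seed = 1)

# analytic StO2 (corrected absorbance + 555/575 nm solve)
sto2_two_wavelength(corrected_absorbance(r), tab)$sto2
#> [1] 0.7983902

# inversion benchmark
inv <- invert_reflectance(r, probe_geometry(1), tab)
inv
#> <inversion_result: StO2 0.806, [THB] 3.61 mg/mL, SSE 0.0304, converged after 8 iter>
band_mean(inv$fitted_props, "mua")    # 400-600 nm mean, cm^-1 (truth: 4.467)
#> [1] 4.462777

# hemoglobin ratio
thb_ratio(r)
#> [1] 1.815959
```

The analytic estimate (0.798) and the inversion (0.806) agree with the
simulated truth (0.80); the recovered band-mean absorption matches the
phantom's construction to 0.1%, and the 584/545 ratio is the raw input to a
phantom calibration (`calibrate_thb`).

A command-line interface wraps the same functions
(`inst/cli/tissuespec simulate | invert | sto2 | thb | correct-fluor |
optimize-powers | kinetics`); every run logs its config hash and seed.

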