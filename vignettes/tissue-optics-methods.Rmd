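---
title: "Models and methods behind tissuespec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tissuespec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
```

tissuespec processes diffuse reflectance and fluorescence spectra from
short-separation fiber probes into vascular endpoints (hemoglobin oxygen
saturation StO2, total hemoglobin concentration [THB]), intrinsic probe
fluorescence, and uptake-kinetic endpoints. This vignette documents the
models, the tunable parameters, the synthetic test bed, the numerical
choices, and the limitations — the information a user needs to judge what a
passing test suite does and does not demonstrate.

## The hemoglobin extinction table

All absorption modeling rests on molar extinction spectra of oxy- and
deoxyhemoglobin. The package ships a **synthetic** table
(`inst/extdata/hb_extinction_synthetic.txt`, loaded by `load_extinction()`):
a Gaussian-band construction that reproduces the canonical features of the
published compilations — a blue (Soret-side) tail, the oxyhemoglobin
beta/alpha bands near 542/576 nm, the broad single deoxyhemoglobin band near
555 nm, a deoxy-dominant red tail, and isosbestic crossings engineered near
522, 545, 570 and 584 nm. It is constructed, not measured, and is labelled
accordingly; absolute values differ from laboratory compilations, but every
algorithm in the package is validated by *self-consistent recovery* against
this same table, for which only internal consistency matters. Users with a
preferred measured compilation can load it from the same three-column text
format.

Two conventions are fixed in one place and used everywhere:

* extinction is **base-10**, so absorption is
  `mua = ln(10) * (C_HbO2 * eps_HbO2 + C_Hb * eps_Hb)` and the corrected
  absorbance uses `log10`;
* hemoglobin molar mass is 64,500 g/mol (tetramer), converting mg/mL to
  molarity.

The table's band-mean oxyhemoglobin extinction over 400–600 nm was fixed at
~32,200 M⁻¹cm⁻¹ so the reflectance phantom design (below) spans band-mean
absorption of about 1.0–7.3 cm⁻¹ across its stated hemoglobin range — the
two published ranges for these phantoms are mutually inconsistent by a few
percent under linearity, and the hemoglobin concentrations were taken as
primary.

## Forward reflectance kernels

Simulation and inversion share a pluggable semi-infinite forward kernel
(`forward_reflectance()`), with two implementations:

* **`short_sds`** (default) — an empirical sub-diffuse modified
  Beer–Lambert model,
  `R = S(musp, rho) * exp(-mua * L(musp, rho))`, with scattering-only escape
  factor `S = x/(1+x)/(4 pi rho^2)`, `x = (musp*rho)^1.3`, and effective
  path `L = rho * (1.8 + 0.15 * musp * rho)`. At separations comparable to
  the transport mean free path (1.5–3 mm against 1/μt′ of 0.5–1 mm here),
  detected photons travel geometry-dominated "banana" paths whose length
  depends only weakly on absorption and scattering. The constants were set
  from two physical targets: differential path-length factors near 2, and a
  weak (order 10–20%) scattering dependence of the path. This is the regime
  assumption under which the corrected-absorbance algebra (a wavelength-
  independent ⟨L⟩ cancelling in StO2) is valid at all, so the simulator and
  the analytic estimators make the *same* physical assumption — which is
  also how the real instrument class this package models is operated.
* **`diffusion`** — the steady-state diffusion-approximation dipole with
  extrapolated boundary (refractive mismatch 1.4). The textbook far-field
  model, retained for comparison and for users at larger separations. At
  1.5 mm with μa up to 7.5 cm⁻¹ its effective path length varies strongly
  with absorption (~16% between 555 and 575 nm over the phantom range),
  which biases the two-wavelength StO2 solve by up to ~0.3; this is a
  statement about the kernel's regime, not about the estimator. Round-trip
  inversion remains exact under either kernel because simulation and
  inversion always share it.

Fluorescence is simulated with a Born-type product model: emitted intensity
= concentration × unit Gaussian emission lineshape × excitation transport
weight (kernel reflectance at the excitation filter peak: 450 nm for the
glucose analog, 550 nm for the mitochondrial probe) × emission escape weight
(kernel reflectance at each emission wavelength). Lineshapes are Gaussian —
peak 545 nm / FWHM 40 nm and peak 580 nm / FWHM 35 nm — clipped to the
acquisition windows 520–600 and 565–650 nm; the peaks and widths are package
choices placed inside the stated windows. This model produces exactly the
distortion class the ratio-metric correction is designed to remove, which
is the point of the test bed.

## The phantom designs (synthetic test bed)

`make_phantom_set()` emulates a two-part tissue-mimicking phantom study with
1 nm wavelength resolution on 400–680 nm (the acquisition band is 450–650 nm;
the simulator extends to 680 nm so the 620–680 nm scattering-baseline band
of the corrected absorbance is available — the two published band
specifications are inconsistent with each other):

* **Reflectance design**: 2 scattering levels (band-mean μs′ of 10 and
  20 cm⁻¹ over 400–600 nm, power-law exponent 1) × 7 hemoglobin additions,
  0.9–6.3 mg/mL in equal steps (the seven individual values are not
  published; equal spacing is this package's choice), fully oxygenated
  (hemoglobin in aerated water), measured by both channels — 14 phantoms.
* **Fluorescence design**: 3 absorption levels (band-mean μa 1.5, 3.0,
  4.5 cm⁻¹) × 2 scattering levels × 3 concentrations (2/4/6 μM glucose
  analog, 30/60/90 nM mitochondrial probe), each with a paired reflectance
  spectrum — 18 phantoms per probe.

Noise is multiplicative Gaussian, `value * (1 + N(0, sd))` clipped at zero,
default `sd = 0.01` (the realistic study condition; exactness tests pass 0).
Every draw derives deterministically from the run seed, and seeded runs are
byte-identical — reproducibility is itself a tested contract.

Kinetic traces use a two-rate uptake model
`I(t) = A (1 - exp(-k_in t)) exp(-k_out t)` post-injection (mitochondrial
probe injected at experiment-clock 0, glucose analog at 20 min), with
closed-form peak time `ln(1 + k_in/k_out)/k_in` used as the oracle for the
delivery-rate estimator. The published uptake curves are not parameterized;
this functional form (fast delivery, slow washout, single interior maximum)
is the package's choice, with defaults `k_in = 0.15/min`, `k_out = 0.01/min`
giving a peak near 18.5 min.

What the test bed does *not* emulate: instrument spectral response beyond a
flat calibration, fiber-bundle averaging over many source–detector pairs,
layered or heterogeneous tissue, other absorbers (water, lipid, melanin,
cytochromes), photobleaching, and probe pharmacokinetics beyond the two-rate
form. Passing recovery tests therefore demonstrates algorithmic
correctness and internal consistency, not instrument-grade accuracy on real
tissue.

## The estimators and their numerical choices

**Inversion** (`invert_reflectance`): bounded Levenberg–Marquardt least
squares (ftol = ptol = 1e-10, ≤500 iterations) on unweighted reflectance
residuals over 450–650 nm, parameterized as (C_Hb, C_HbO2 in μM, scatter
amplitude at 550 nm, scatter exponent) with bounds ([0,300] μM, [1,60] cm⁻¹,
[0,4]). Multistart: one data-driven start (amplitude solved from the red end
of the spectrum where hemoglobin absorption is weak, exponent 1) plus a
5-point Latin-hypercube design with a fixed seed; ties resolve to the lowest
SSE, then the lowest total hemoglobin (parsimony). The returned SSE is never
worse than the first start (descent contract), and failures return
`converged = FALSE` rather than an exception.

**Corrected absorbance / two-wavelength StO2**: the baseline is an ordinary
least-squares line of `log10(1/R)` against wavelength over 620–680 nm — the
ordinate choice makes the equation dimensionally coherent, and scale
invariance (any gain on R cancels) is tested. The 2×2 solve at (555, 575) nm
refuses condition numbers above 1e6; negative path-scaled concentrations are
clamped to zero with a flag (noise at low hemoglobin routinely produces
small negatives), which also makes pure-component inputs return exactly 1
or 0.

**[THB] ratio**: single 1-nm node values at 584 and 545 nm by default (the
published "narrower bandwidth" is unspecified); a ±2 nm band mean is
available. Calibration is linear by default (quadratic available), refuses
fewer than 3 phantoms, degenerate hemoglobin values, or a fitted mapping
that is non-monotone over the data range, and flags extrapolation beyond
1.2× the calibrated ratio range.

**Fluorescence correction** (`optimize_powers`): the published criterion —
corrected spectra should "converge" across optical-property combinations at
equal concentration — does not name an objective. The package minimizes the
summed squared coefficient of variation of corrected peak-band intensity
across combinations, summed over concentration levels: scale-free, so the
arbitrary overall gain of corrected intensities cannot be exploited by the
optimizer. Search is Nelder–Mead from (0,0), iteration budget 2000, relative
tolerance 1e-10, restarted once from the first optimum, and the result is
never accepted if worse than (0,0). Powers are stored per (fluorophore,
channel) — they are system-dependent and must not be shared across channels.
R_ex is read at the excitation filter center (not the local reflectance
maximum — a declared choice), R_em at the configured emission peak, nearest
grid node within 0.5 nm.

**Kinetics**: endpoints use the nearest sample within ±2 min of the target
time (the published endpoints are sampled values, not interpolations);
delivery rate uses the first time attaining the maximum, with ties at t = 0
deferring to later samples and a peak strictly at injection time being an
error. Baseline spectra, when supplied, are subtracted point-wise in
spectrum space before correction. Group comparison defaults to the Welch
(unequal-variance) t-test with a pooled-variance switch.

## Problem sizes and runtime

The benchmark suites are desk-scale by construction: 14 reflectance phantoms
× 2 channels and 18 fluorescence phantoms × 2 probes, 1 nm grids, six-start
inversions — the full test suite runs in seconds and the acceptance script
in well under a minute on one CPU. These sizes are the phantom study's own
design, and the statistical behavior at 1% noise is far inside the stated
error bounds, so larger replications were not needed.

## Known limitations

* The extinction table is synthetic; absolute concentrations from real
  instrument data require loading a measured compilation and re-calibrating.
* The `short_sds` kernel constants (path factor ~2, weak scattering
  dependence) are representative, not fitted to any instrument; absolute
  reflectance units are arbitrary-calibrated.
* [THB] from the inversion is reported in mg/mL on the model scale; the
  ratio method reports whatever scale its calibration was built on.
* The two-wavelength StO2 assumes the wavelength pair is well-conditioned
  against the loaded table; alternative pairs are configurable but not
  auto-selected.
* Multi-absorber media (beyond the two hemoglobin species) are out of scope.
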