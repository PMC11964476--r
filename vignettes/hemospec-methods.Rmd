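---
title: "Spectroscopic hematology with hemospec: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectroscopic hematology with hemospec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemospec)
```

## The problem

Fluorescence and absorption spectroscopy of whole blood offers a rapid,
noninvasive complement to the complete blood count (CBC). A 200–900 nm
trace of a diluted blood sample carries three diagnostically readable
regions: hemoglobin/oxyhemoglobin absorption at 400–600 nm,
deoxyhemoglobin at 600–700 nm, and plasma/water at 800–900 nm. An
excitation–emission matrix (EEM) adds a second axis and resolves the
endogenous fluorophores — tryptophan, NADH and flavins — whose relative
intensities report protein content and metabolic state.

`hemospec` implements this analysis end to end: a synthetic-data
generator standing in for raw instrument exports (which are not
publicly deposited for this kind of clinical study), the standard
preprocessing chain, closed-form photophysics and erythrocyte
biophysics, and a band-level two-patient comparison cross-validated
against CBC values.

## Models

### Photophysics

The closed forms are deliberately simple, linear-regime expressions:

* fluorescence intensity $I = \Phi\, I_0\, C\, \epsilon$ (quantum
  yield × lamp power × concentration × molar absorptivity);
* Beer–Lambert absorbance $A = \epsilon C l$ with transmitted fraction
  $10^{-A}$; inverted at 540 nm and scaled by hemoglobin's molar mass
  (64 500 g/mol) to estimate g/L hemoglobin;
* Stokes shift $\Delta\lambda = \lambda_{em} - \lambda_{abs}$
  (anti-Stokes inputs are an error, not a silent negative);
* band intensity $I_{total} = \int I(\lambda)\,d\lambda$, trapezoid on
  the native grid with interpolated endpoints, no resampling;
* penetration depth $d = 1/(\epsilon C)$, returned verbatim. Note this
  reciprocal omits the $\ln 10 \approx 2.303$ factor a base-e $1/e$
  attenuation depth would carry; treat it as a relative index.

The default $\epsilon_{540} = 54\,000$ L mol⁻¹ cm⁻¹ is a configurable
placeholder of the right order of magnitude, not a literature constant;
calibrate it before quantitative use.

### Erythrocyte biophysics

* shape factor $= I_{peak}/R$ (a.u./µm; lower → more biconcave);
* deformability index, either from scattering
  ($\int I_{scat}\,d\lambda / R$) or from zeta potential via an
  exponential model $a e^{b\zeta} + c$ or a logarithmic model
  $a \ln(-\zeta) + c$ with defaults $a = 1.5$, $b = -0.05$ per mV,
  $c = 0.5$. The logarithm is taken on the numeric mV magnitude — the
  source convention leaves the reference unit undefined, so this is a
  documented convention, not physics;
* DLVO interaction energy
  $E_{total} = \pi \epsilon_m R \zeta^2 e^{-\kappa d} - A_H R/(12 d)$
  in SI units (J), with the sign of $E_{total}$ separating
  repulsion-dominated (stable) from attraction-dominated (aggregating)
  regimes; the exact zero is classified as repulsion-dominated;
* empirical sizing $R = k\,\lambda_{peak}$ with default
  $k = 0.009$ µm/nm, chosen so the 6–8 µm physiologic diameter range
  maps into the 667–889 nm instrument window. $k$ is a calibration
  constant with no universal value.

Symbol collisions in the source conventions (absorptivity vs
permittivity, path length vs separation, absorbance vs Hamaker
constant) are resolved by distinct argument names throughout.

### Diagnostics

`band_summary()` integrates the three named regions; the 700–800 nm
interval belongs to no named band and is reported separately as
`band_unassigned`. `compare_patients()` declares a winner per band with
a 1% relative tie threshold (the source material never quantifies
"higher") and maps winners onto a closed interpretation vocabulary, so
report text is deterministic and testable. `rbc_count()` and
`implied_mch()` are exact algebraic inverses
(RBC = total Hb / MCH); `mch_reference_range()` implements the
age-binned MCH table (24–30, 26–32, 26–34, 27–34 pg), bins closed on
the left and open on the right, with ages ≥ 45 reusing the adult bin
since nothing older is tabulated.

`cbc_concordance()` checks each spectral winner against the CBC
ordering: hemoglobin for the 400–600 nm band, *inverse* hematocrit for
the plasma band (more plasma ⇔ lower hematocrit). The deoxyhemoglobin
band has no CBC counterpart — it reflects real-time oxygen
dissociation, not cell counts — and is always flagged
`functional-only`.

## The synthetic-data generator: what it emulates, what it does not

All peaks are Gaussians. The source conventions give band *ranges*, not
line shapes, so centers sit at range midpoints (tryptophan ex 290 /
em 345; NADH ex 350 / em 455; flavins ex 460 / em 525 nm) and sigmas at
half the range widths. No quantum yields, absorptivities or
concentrations are published for this system; the library's amplitudes
were fixed once so that the NADH component dominates the EEM, matching
the observed hierarchy of fluorescence activity, and are not tuned
further.

The hemoglobin absorption simulation is a *single* band at 550 nm whose
height grows strictly with oxygen fraction and decays exponentially
with glycation (HbA1c %), broadening as it fades. This reproduces the
simulated behavior the analysis targets; it is **not** the
literature two-band (541/577 nm) oxyhemoglobin spectrum, and green
tests establish internal consistency with the stated model only.

Patient spectra superimpose three Gaussian band components (540, 650,
850 nm) with amplitudes proportional to Hb × SpO₂, Hb × (1 − SpO₂) and
plasma fraction, scaled by the lamp power at each band center and by a
lifecycle multiplier (young 1.25 > mature 1.0 > old 0.65). Lamp
profiles are idealized smooth curves (deuterium UV-weighted, halogen
NIR-weighted, their sum, and a band-limited UV lamp); they are not
radiometric models of real bulbs. Under UV excitation the
deoxyhemoglobin component enters with negative sign — emulating the
background-subtracted negative excursions seen experimentally — and
noise is left unclipped there, while emission noise under other lamps
clips at zero. Band comparison under UV therefore uses absolute
integrals, a documented resolution of a genuine ambiguity in the source
description.

CBC records are built the other way around from real analyzers: MCH is
drawn uniformly in the age bin (deficiency conditions push it outside
the bin, direction-only), RBC and MCV come from physiologic ranges, and
Hb and Hct are *derived* (Hb = RBC × MCH / 10, Hct = RBC × MCV / 10),
so every record is exactly self-consistent. Real data have measurement
error between these quantities; the generator does not emulate that.

Noise everywhere is additive white Gaussian with user-set sd — no
detector nonlinearity, wavelength jitter, or stray-light structure.

## Preprocessing: choices and their limits

The chain is maximum-intensity normalization → baseline correction →
Gaussian smoothing, an order fixed here because the source lists the
stages without one. Normalization divides by the maximum *absolute*
intensity so UV-difference spectra with negative lobes normalize
stably.

The baseline estimator is morphological opening (rolling minimum then
rolling maximum over a 50 nm default window) followed by Gaussian
smoothing of the estimate. Opening tracks constant and linear
backgrounds exactly and ignores peaks *narrower than the window*; for
peaks wider than roughly half the window the estimate creeps up the
peak flanks. Two consequences worth knowing:

* choose `window` ≳ 5–6× the peak sigma (or the widest peak you want
  preserved);
* the chain cannot be exactly idempotent at the defaults: the 50 nm
  window wants peak sigmas below ~8 nm while the 2 nm smoothing kernel
  shaves more than 1% off any peak narrower than ~14 nm. The
  idempotence test therefore uses a 20 nm-sigma peak with a 200 nm
  window, parameters at which both error terms drop below 1%.

Peak fitting refines local maxima (5% prominence default) by local
single-Gaussian least squares with a moment-based fallback and a
sanity gate on divergent fits; there is no multi-peak deconvolution of
overlapping bands. EEM assignment searches a ±3-width window around
each library fluorophore and refines by separable 1-D fits, which is
exact for noise-free separable Gaussians and adequate at SNR ≥ 20
(center RMSE below one grid step over 100 seeded replicates, verified
in the test suite).

## The two-patient pipeline and a deliberate discrepancy

`run_pipeline()` simulates (or ingests) two patient spectra,
preprocesses them, and compares bands. One deviation from a literal
reading of the preprocessing chain: the two spectra are normalized by
their *shared* maximum, not per-spectrum. Per-spectrum max scaling pins
both dominant bands at exactly 1 on clean synthetic data and destroys
the cross-patient amplitude ordering the comparison exists to measure;
joint scaling is the standard way to compare samples on one intensity
scale. Single-spectrum work (`preprocess_spectrum()`) keeps the
per-spectrum convention.

The bundled demonstration pair gives patient 1 higher hemoglobin,
near-complete oxygenation *and* more plasma, and patient 2 lower
oxygenation with less plasma — the pattern of the combined
deuterium+halogen comparison. Cross-validating that pattern against the
demonstration CBC (patient 1: Hb 16.4 g/dL, Hct 46.9%; patient 2:
12.6 g/dL, 38.5%) flags the plasma band `disagree`: spectroscopy under
this lamp assigns patient 1 the higher plasma signal while the CBC
gives patient 1 the higher hematocrit. This mirrors a real,
source-level inconsistency between lamp configurations (the
halogen-only comparison flips the plasma band), and the package
reports it honestly rather than harmonizing it. The hemoglobin band
agrees under every configuration; the deoxyhemoglobin band is
functional-only by design.

## Numerical notes

* Integration: trapezoid on the native grid; interpolated endpoint
  samples make band integrals exactly additive over adjacent windows.
* Smoothing: discrete Gaussian kernel, radius 4σ, reflective
  boundaries, kernel normalized so constants pass through exactly;
  σ = 0 is a bit-exact identity.
* Ties: `compare_patients()` uses relative difference against the
  larger magnitude; the zero/zero case is a tie.
* Seeds: every generator takes an explicit seed and restores the
  caller's RNG state; `run_pipeline()` derives per-stage child seeds
  from the global seed so adding a stage never perturbs earlier draws.
* File I/O writes 15 significant digits, keeping round trips faithful
  to 1e-12 relative.

## Known limitations

* No Mie theory: sizing is the empirical $R = k\lambda_{peak}$ only.
* No fluorescence lifetimes, no PCA classification, no multi-component
  spectral unmixing.
* No model of temperature/osmolarity/hypoxia stress surfaces for
  deformability — no governing equations exist for them in the source
  material.
* The synthetic world is Gaussian-band and noise-additive; green tests
  demonstrate correctness of the pipeline on that world, not
  instrument-level realism.
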