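---
title: "Modeling ratiometric Mg2+ sensing: speciation, spectra, and fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ratiometric Mg2+ sensing: speciation, spectra, and fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magsense)
```

## The problem

Wavelength-ratiometric fluorescent indicators report an analyte through
the ratio of emission intensities in two detection channels, which cancels
probe concentration, path length and source fluctuations. For a
quinoline-dicarboxylate Mg2+ sensor such as MagZet1 the quantitative story
involves several coupled layers:

1. **Chemical speciation.** The sensor partitions among its metal-free,
   protonated, Mg-, Ca- and Zn-bound forms, while Mg2+ itself is buffered
   by cellular ligands (dominantly ATP). Each equilibrium is summarized by
   an apparent dissociation constant valid in the stated buffer
   (50 mM PIPES, 100 mM KCl, pH 7.0): Kd,Mg = 0.14 mM at 25 °C
   (0.088 mM at 37 °C), Kd,Ca = 1.7 mM, Kd,Zn = 2.6 nM, pKa = 7.1,
   Kd(MgATP) = 50 µM and a weak ternary sensor·Mg·ATP complex at 100 mM.
2. **Photophysics.** Each species has an emission profile and a
   brightness ∝ εφ; channel intensities are concentration-weighted sums
   of band integrals over the channel passbands.
3. **Inference.** Constants are estimated from titrations by nonlinear
   least squares; cellular readouts are per-cell ratios compared across
   populations.

The package implements each layer as a module and ties them together with
synthetic-data generators carrying machine-readable ground truth, so the
whole chain is testable end to end without any measured data.

## The speciation model

A system is a set of components (sensor, metals, ligands, optionally a
proton) plus stepwise assembly reactions, each parameterized by a
dissociation constant

$$K_d = \frac{\prod_i [X_i]_{\text{free}}^{\nu_i}}{[\text{product}]}.$$

Products may feed later reactions — MgATP is assembled first and the
ternary complex forms as S + MgATP ⇌ S·Mg·ATP. The solver
(`solve_speciation()`) performs damped Newton iteration on the logarithms
of the free concentrations of the mass-balanced components (positivity is
automatic), with a per-component bisection sweep as fallback when a Newton
step fails to reduce the residual. Convergence demands a maximum relative
mass-balance residual of 1e-9 within 200 iterations; failure is reported
through `converged = FALSE` with the residuals attached, never silently.
The initial guess is half of each total. Components with zero total are
held at zero; a proton component is clamped at `10^-pH` (buffered
systems), so protonation consumes no proton mass balance.

Numerical choices worth knowing:

* All concentrations are molar internally; config files carry explicit
  unit tags (`mM`, `uM`, `nM`) converted on load.
* The 1:1 case has the closed-form quadratic solution
  (`closed_form_1to1()`), implemented in the cancellation-stable form
  `2ac/(b + sqrt(b^2 - 4ac))`; solver and closed form agree to 1e-9
  across a 20×20 log grid of totals and constants spanning nM–M, and the
  three-reaction system is checked against an independent nested-bisection
  oracle.
* Constants carry temperature labels; no van't Hoff interpolation is
  attempted (only 25 °C and 37 °C point values exist).
* Activity corrections, multi-protic ATP species (HATP³⁻ …) and kinetics
  are out of scope: constants are apparent values at the stated ionic
  background.

Protonation and metal binding are modeled as strictly competitive for the
free sensor. This is a deliberate simplification: measured pH profiles in
the presence of 1 mM Mg2+ stay flat further into acidic pH than a strictly
competitive model predicts, suggesting partial independence of the two
sites. We record this as a model limitation rather than tuning it away;
the pH-invariance checks in the test suite therefore clamp the
deprotonated+bound pool where the distinction matters.

## Spectra and channel composition

Species emission profiles are sums of Gaussian bands scaled by a relative
brightness. The bundled MagZet1 fixture places emission maxima at 500 nm
(free, φ = 40.4%), 530 nm (Mg-bound, φ = 76%), 520 nm (Ca-bound), 545 nm
(Zn-bound) and 630 nm (protonated). Band widths (σ = 34 nm, ≈80 nm FWHM)
and the Ca-/Zn-bound and protonated brightness values are synthetic
modeling choices — those quantum yields were never determined
experimentally — and must not be read as measured values. The protonated
form is nearly nonemissive and far red-shifted, which is exactly why the
F530/F500 ratio is pH-stable: the acidic form simply drops out of both
passbands.

Channel intensities integrate each spectrum over the passband by the
trapezoid rule on a 1 nm grid; single-wavelength readouts (F500, F530)
are 1 nm-wide passbands, and the flow-cytometry configuration uses 450/50
and 530/30 bandpass filters under 405 nm excitation. Excitation
wavelength is metadata: in vitro work fixes excitation at the 390 nm
isosbestic point, so excitation-dependent efficiency differences are
folded into per-species brightness.

The ratio calibration follows the standard ratiometric inversion

$$[\mathrm{Mg}]_{\text{free}} = K_d \, \beta \,
  \frac{R - R_{\min}}{R_{\max} - R},$$

with β the free/bound brightness ratio in the denominator channel. With
this convention the half-saturation ratio is
$R = (\beta R_{\min} + R_{\max})/(\beta + 1)$, which the round-trip tests
verify to 0.1% across four decades of free metal.

## Fitting: what is identifiable, and what is not

All positive parameters are fitted on the log scale via
Levenberg-Marquardt (`minpack.lm::nls.lm`); standard errors come from the
Jacobian at the optimum with delta-method back-transformation, and
replicate-level spread is reported as the SD of per-replicate refits when
triplicates are present, mirroring the usual "average of three
independent titrations ± SD" convention.

Two genuine identifiability issues shaped the API:

* **Kd versus β.** In the tracer regime (sensor ≪ Kd) the ratio isotherm
  is $R(m) = (\beta K_d R_{\min} + m R_{\max})/(\beta K_d + m)$: only the
  product $\beta K_d$ is identifiable. `fit_kd_ratio()` therefore takes β
  from the spectral calibration and holds it fixed by default; freeing it
  (`beta = NULL`) is sound only when ligand depletion is appreciable. The
  fit itself always includes depletion through the exact 1:1 mass
  balance, which is what makes nanomolar constants (Zn at micromolar
  sensor) recoverable at all. The titration generator centers its default
  15-point log grid on the depletion-corrected half-saturation total
  `kd + s_total/2` for the same reason.
* **Ternary constant versus ternary brightness.** The ternary complex
  shares the Mg-bound chromophore state, so in the weak-binding limit its
  ratio contribution scales as (brightness scale)/(ternary Kd).
  `fit_ternary()` holds the scale at its calibrated value by default
  (`fit_scale = TRUE` frees it for low-noise data) and profiles the RSS
  over the two decades above the estimate on a fixed 40-point log grid:
  a profile flat to within 1% of the noise floor — or an estimate pinned
  at the upper bound — flags the result `non_identifiable`, in which case
  the estimate is a lower bound. Pure-competition data are correctly
  flagged this way.

The pKa fit uses the sigmoidal single-site model
$I(\mathrm{pH}) = (I_{\text{acid}} + I_{\text{base}}
10^{\mathrm{pH}-pK_a})/(1 + 10^{\mathrm{pH}-pK_a})$; flat series are
rejected as uninformative and fits whose inflection lies outside the data
range are flagged. Starting values throughout are data-driven: the ratio
extremes set $R_{\min}/R_{\max}$, the half-range crossing sets the
half-saturation point.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the study's experimental designs with known
truth: 1:1 metal titrations with triplicate Gaussian noise (SD defaulting
to 1% of each channel's dynamic range — per-point noise magnitudes were
never published, so this is a declared default, not an inference), pH
series over pH 5–8 under the three-species protonation model, equimolar
MgATP competition series (0.1–50 mM) with and without the ternary
pathway, and per-cell two-channel populations with log-normal dye loading
(σ_log = 0.5; AM-ester loading heterogeneity is unquantified) and
log-normal free-Mg spread (CV 10%). The standard cell arms are vehicle
(free Mg 0.5 mM, mid-physiological), EDTA-depleted (≈0) and
ionophore + 50 mM Mg (saturating). Every table carries its generating
parameters in a `truth` attribute (and JSON sidecar on disk); recovery
tests read truth only from the sidecar.

What passing these tests shows is *self-consistency*: the estimators
recover the constants that generated the data, at the study's designs and
noise levels. Real titrations add baseline drift, inner-filter effects,
pipetting error structure and spectral baselines that the Gaussian noise
model does not emulate, so the recovery tolerances here are lower bounds
on real-world uncertainty.

## Population statistics

Per-cell ratios are background-corrected channel quotients; events whose
corrected denominator is non-positive are excluded and counted in a QC
report. Because loading is multiplicative in both channels it cancels in
the ratio, and all ratio statistics are invariant to global channel gain.
Population comparisons use a chi-square homogeneity test on shared bins:
64 equal-width bins over the pooled central 99% range, adjacent bins
merged until every expected count is ≥ 5 (the standard validity rule),
p-values from the chi-square distribution with (bins − 1) degrees of
freedom. The published analysis did not specify its binning or software,
so this is the package's own documented convention, calibrated in the
test suite (identical samples give statistic 0, p = 1; same-generator
pairs at n = 1000 give p > 0.001 in ≥ 99/100 comparisons; a 20% median
shift at 10% CV is detected at p < 0.001). Imaging-style small-n
comparisons use the two-sided Welch t test with a defined p = 1 for the
degenerate equal-constant case. No scatter-based gating is implemented; a
pass-through hook on the event table is the extension point.

## Problem sizes and defaults

The defaults keep every stage at desk scale: 15-point titrations in
triplicate, 13-point pH series, 15-point MgATP series, 1000 events per
cell population, 40-point identifiability profiles, a 20×20 oracle grid
and 50 random ternary systems for solver validation, and 100 same-
generator pairs for the chi-square null calibration. The full test suite
runs in well under a minute.

## Known limitations

* Strictly competitive protonation (see above); no partially independent
  protonation site.
* Apparent constants only: no ionic-strength or activity corrections, no
  multi-protic ATP speciation, no temperature interpolation.
* The Gaussian band model is a shape assumption; measured emission
  profiles are asymmetric, and Ca-/Zn-bound brightness values are
  placeholders.
* No excited-state modeling (ICT/TICT), inner-filter correction or
  photobleaching; FCS files are not parsed — per-event tables are CSV.
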