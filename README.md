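# magsense

Quantitative machinery for wavelength-ratiometric fluorescent metal-ion
indicators, built around a quinoline-dicarboxylate Mg²⁺ sensor
(MagZet1). The package is aimed at chemists and cell biologists who
calibrate such probes and interpret their cellular readouts: it models
the coupled chemistry (sensor, H⁺, Mg²⁺, Ca²⁺, Zn²⁺, ATP, ternary
sensor·Mg·ATP complexes), predicts two-channel fluorescence ratios from
speciation states, estimates binding and protonation constants from
titrations, and compares per-cell ratio populations from imaging or flow
cytometry.

## What it computes

* **Equilibrium speciation.** `solve_speciation()` solves the coupled
  mass balances of an `equilibrium_system()` — components plus stepwise
  assembly reactions, each with a dissociation constant
  `Kd = Π[free reactants]/[product]` — by damped Newton iteration on log
  free concentrations (relative residual ≤ 1e−9), with `closed_form_1to1()`
  providing the exact 1:1 quadratic special case.
* **Photophysics.** Species spectra are Gaussian band sums with
  brightness ∝ εφ; `compose_channel_intensities()` turns a speciation
  state into channel intensities and the ratio R (e.g. F530/F500, or
  530/30 vs 450/50 bandpass for flow cytometry). The standard
  calibration `[Mg]free = Kd·β·(R − Rmin)/(Rmax − R)` is implemented as
  `ratio_to_free_metal()`.
* **Fitting.** `fit_kd_ratio()` (apparent Kd′ from ratio titrations,
  ligand depletion included), `fit_pka()` (sigmoidal protonation model),
  `fit_ternary()` (binary + ternary competition model over full
  speciation, with an identifiability screen), plus
  `selectivity_ratio()`/`selectivity_panel()`.
* **Cell statistics.** `per_cell_ratio()` (background-corrected, with QC
  of degenerate events), `compare_populations_chi2()` (shared-bin
  homogeneity test) and `two_group_ttest()`.
* **Synthetic data.** `gen_titration_series()`, `gen_ph_series()`,
  `gen_mgatp_series()` and `gen_cell_population()` regenerate every
  study design with known ground truth carried in a `truth`
  attribute/JSON sidecar, so the whole pipeline is testable offline.

The bundled preset (`magzet1_config_path()`, `magzet1_constants()`)
encodes the sensor's published constants: Kd,Mg 0.14 mM (25 °C) and
0.088 mM (37 °C), Kd,Ca 1.7 mM, Kd,Zn 2.6 nM, pKa 7.1, Kd(MgATP) 50 µM
and the 100 mM ternary complex.

## Worked example

Simulate a triplicate Mg²⁺ titration at 1% channel noise and re-fit it:

```r
library(magsense)

tab <- gen_titration_series(kd = 0.14e-3, s_total = 10e-6,
                            noise_sd = 0.01, replicates = 3, seed = 1)
truth <- attr(tab, "truth")
fit <- fit_kd_ratio(tab, s_total = truth$s_total, beta = truth$beta)
fit
#> Nonlinear least-squares fit (converged, n = 45, RSS = 0.003967)
#>        estimate         se
#> kd    0.0001413 3.4303e-06
#> r_min 0.6798700 3.7385e-03
#> r_max 1.4778000 3.3180e-03
#> Fixed: s_total = 1e-05, beta = 0.784561591858344
```

The recovered Kd (0.141 mM) sits within one standard error of the
generating 0.14 mM; `r_min`/`r_max` are the ratios of the fully free and
fully Mg-bound sensor, and β is the free/bound brightness ratio in the
denominator channel, fixed from the spectral calibration
(`ratio_bounds()`).

Selectivity and a cell-population comparison:

```r
cst <- magzet1_constants()
selectivity_ratio(cst$kd_ca, cst$kd_mg_25)
#> [1] 12.14286   # >= 10-fold preference for Mg over Ca

ev <- gen_cell_population(n_cells = 1000, seed = 2)  # vehicle/EDTA/ionophore arms
r  <- per_cell_ratio(ev, "BP530", "BP450")
compare_populations_chi2(r$ratio[r$group == "edta"],
                         r$ratio[r$group == "vehicle"])
#> Chi-square population comparison
#>   n: 1000 vs 1000; medians: 1.106 vs 4.472
#>   X-squared = 2000, df = 11, p = 0
```

The Mg-depleted arm collapses toward the metal-free ratio (≈1.09 in the
flow channels) while vehicle cells at 0.5 mM free Mg sit near 4.5; the
shared-bin χ² test separates the populations decisively.

See `vignettes/ratiometric-mg-sensing.Rmd` for the model, its
assumptions, identifiability caveats and numerical choices.

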