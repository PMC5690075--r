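# oculardose

Proton pencil-beam dose simulation for ocular treatments on a
general-purpose scanned beamline.

Uveal melanoma is usually treated on dedicated low-energy proton lines.
`oculardose` models the alternative studied at synchrotron facilities:
take an actively scanned, general-purpose beamline (63–250 MeV, built for
deep-seated tumors), move the treatment isocenter close to the nozzle to
shrink the air gap, degrade the beam with a PMMA range shifter so the
Bragg peak lands at ocular depths, and sharpen the field edge with a
patient-specific brass collimator. The package lets a medical physicist
reproduce every commissioning observable of that adaptation — ranges,
transverse beam widths, lateral penumbra, spread-out Bragg peak (SOBP)
shape, and per-structure dose-volume histograms on an anatomical eye
phantom — with fast closed-form physics in place of condensed-history
Monte Carlo.

## The models in brief

* **Range–energy**: the Bragg–Kleeman rule `R = α E^p`, least-squares
  fitted in log–log space to the measured beamline calibration points
  (`fit_range_energy()`, `cnao_range_model()`).
* **Depth dose**: analytic Bragg curves from the power-law stopping model
  `s(R−z) = (R−z)^{1/p−1}` convolved with Gaussian range straggling
  `σ = 0.012 R_cm^0.935` (evaluated on the *total* water-equivalent range
  when a degrader is present), plus the source's 0.05% energy spread
  (`pristine_depth_dose()`).
* **Transverse transport**: Fermi–Eyges moment propagation through the
  line's material budget (exit window, monitor-chamber foil stacks, air,
  range shifter), with Highland multiple-Coulomb-scattering kicks
  `σ_θ = 13.6 MeV/(βpc) · √(x/X₀) · (1 + 0.038 ln(x/X₀))`
  (`fwhm_at()`, `highland_sigma()`).
* **SOBP design**: distal-to-proximal plateau-filling weights
  `w_j = (H − Σ_{k<j} w_k h_k(b_j)) / h_j(b_j)` with a non-negative
  least-squares ripple refinement (`compute_sobp_weights()`,
  `sobp_plan_for()`).
* **Delivery**: 3 mm-step scanned spots over a 40×40 mm² field, optional
  elliptical brass collimator (mask + conditional drift blur), analytic or
  seeded Monte-Carlo dose on water boxes, the parameterized eye phantom,
  or a synthetic DICOM CT series (`simulate_dose()`, `irradiate_eye()`).
* **Scoring**: FWHM, 80–20% penumbra, plateau uniformity, SOBP
  width/falloff/entrance ratio, cumulative DVHs (`sobp_metrics()`,
  `dvh()`, `prescription_coverage()`).

The methods vignette (`vignettes/methods.Rmd`) documents every model,
default and numerical decision in detail.

## Worked example

Fit the range–energy law to the published calibration, build the
benchmark 10-layer SOBP behind the 43 mm shifter, and score it in the
25 mm water box:

```r
library(oculardose)

m <- cnao_range_model()
m
#> <range_energy_model> R = 0.015406 * E^1.8379 (R in mm, E in MeV)
#>   4 calibration points, max |rel error| 0.408%
range_in_water(m, 100.51)
#> [1] 73.7 (mm; measured benchmark: 74.00)

plan <- sobp_plan_for(distal_range = 35.5, sobp_width = 18, spacing = 2)
dose <- irradiate_water(plan, target = water_box_grid())
dp   <- depth_profile(dose, half_window = 3)
sobp_metrics(tibble::tibble(coordinate = dp$coordinate, value = dp$value),
             plateau_span = range(plan$layers$peak_depth) -
               cnao_depth_offset())
#>   width distal_falloff_80_20 entrance_plateau_ratio flatness
#>   18.25                 1.06                  80.89        2
```

The SOBP is 18.25 mm wide at the 98%-of-plateau level (published:
18.10 ± 0.02 mm), falls from 80% to 20% of the plateau over 1.06 mm
(published: 1.3 ± 0.02 mm), and the water-box entrance sits at 81% of the
plateau (published peak/entrance ratio: 80%). The transverse model,
calibrated only at the exit window and the isocenter, predicts the
intermediate monitor-chamber plane at

```r
fwhm_at(build_standard_layout(81.56), cnao_source(81.56), -654.6)
#> [1] 7.88 (mm; measured: 8.35 ± 0.84)
```

and a 12 Gy fraction delivered at 1 Gy per spill takes
`session_time(prescription_config(dose_per_fraction = 12))` = 67 s.

Plots: `autoplot(plan)` overlays the weighted layers and their sum;
`autoplot(dvh(dose_grid))` draws per-structure DVHs;
`plot_fwhm_validation(81.56)` compares transported and measured beam
widths along the line.

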