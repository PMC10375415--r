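# protorec

Desk-scale simulation and reconstruction toolkit for **in-beam proton
dose-range verification with scattered protons**.

## The problem

Proton therapy concentrates dose at the Bragg peak — the sharp maximum
of energy deposition at the end of the proton range — so millimetre-level
uncertainty in *where* that peak sits translates directly into dose to
the wrong tissue. `protorec` implements a verification concept that
monitors the irradiation itself: dozens of small plastic scintillators
(10 × 10 × 3 mm) placed 1 cm outside the body surface measure the energy
carried out by Rutherford-scattered beam protons, integrated into one
"current" value per detector, and a learned inverse model reconstructs
the 3D dose distribution — in particular the Bragg-peak position — from
that current vector, optionally conditioned on the CT (the voxel mass
density grid).

The forward physics is the textbook chain for protons in matter: the
number of scattered protons follows the Rutherford cross-section

    dσ/dΩ = (Z e² / 4E)² · 1/sin⁴θ,

so the scattering signal grows as E⁻² as the proton slows down, while
the dose range follows Bethe–Bloch stopping. Protons near the peak are
too slow to escape the phantom, so the currents see the entrance channel
but not the peak — which is exactly why supplying the density grid as a
prior improves depth accuracy in heterogeneous geometries, and what the
package's substitution experiment demonstrates quantitatively.

## What is in the package

* **Monte Carlo forward model** (`simulate_irradiation()`): condensed-
  history proton transport on voxel phantoms — Bethe–Bloch slowing down,
  Bohr energy straggling, Highland multiple scattering, hard Rutherford
  scatters sampled from the tabulated inverse CDF — scoring per-voxel
  dose and per-detector currents (analog ray-trace or an expected-value
  point-detector estimator). An energy ledger closes within 1%.
* **Phantom generators**: rectangular water phantoms, random air slabs,
  and body-like cylinders with 3–6 random hydroxyapatite/glass
  structures (`build_rect_phantom()`, `insert_air_layer()`,
  `build_cylinder_phantom()`, `substitute_region()`, `export_ct()`).
* **Detector layouts**: side arrays (24 × 2, 24 × 4) and a 36-column ×
  12-row ring at 10° steps with the 2 cm beam-exclusion rule
  (`place_detectors_rect()`, `place_detectors_cyl()`,
  `select_subset()`).
* **Reconstruction**: dataset generation per study family, 64/16/20
  splits, mirror-flip augmentation with exact detector-id remapping, and
  a fully connected encoder–decoder (LeakyReLU 0.2, tanh output, MSE,
  Adam, batch 4) trained from the R random seed
  (`generate_dataset()`, `split_dataset()`, `augment_flips()`,
  `build_model()`, `train_model()`, `predict()`).
* **Evaluation**: per-axis Bragg-peak position errors, root-sum-squared
  dose error on a 100 Gy normalization, and a brute-force-verified
  global gamma analysis at 3%/3 mm with strict γ < 1 acceptance
  (`peak_errors()`, `delta_dose()`, `gamma_map()`,
  `gamma_passing_rate()`, `evaluate_testset()`).
* **Experiments**: material-substitution current comparison with
  Benjamini–Hochberg control, detector-count reduction curves, and the
  paired with/without-CT ablation (`run_substitution_experiment()`,
  `run_detector_reduction()`, `run_ct_ablation()`).

A thin command-line front end over these functions ships in
`inst/cli/protorec.R`.

## Worked example

A scaled-down family-A study — homogeneous rectangular water phantom
(32 × 20 × 20 cm, 2 mm voxels), pencil beam drawn from 180–220 MeV with
±4 cm horizontal shifts, 48 detectors, 200 samples at 2.5 × 10⁴ protons
each — generated, trained and evaluated in one call:

```r
library(protorec)
set.seed(1)
st <- run_study("A", n_samples = 200, n_protons = 2.5e4)
st$report
#> evaluation over 40 held-out samples
#>  stat dx_peak dy_peak dz_peak delta_dose gamma_pass
#>  mean    3.95    1.05      NA      0.819      96.66
#>   std    3.15    1.11      NA      0.210       1.33
#>   min    0.00    0.00      NA      0.464      93.40
#>   max   12.00    4.00      NA      1.265      99.05
```

Reading: over the 40 held-out test samples, the learned model places
the Bragg peak within one to two 2 mm voxels of the Monte Carlo truth
in depth (mean 3.95 mm at this seed; typical runs land between 2.5 and
4 mm) and within about 1 mm transversely; after normalizing each Monte
Carlo dose to a total of 100 Gy the root-sum-squared voxel error is
≈ 0.8 Gy; and about 97% of voxels pass the 3%/3 mm gamma test against
the Monte Carlo reference. The full-scale system reports sub-voxel
depth accuracy from ~9× the training data; the residual gap here is
data-limited (see the methods vignette). A single-sample forward run is
equally direct:

```r
p <- build_rect_phantom()
b <- beam_spec(200, shift_cm = c(2, 0), width_cm = 1, n_protons = 5e4)
d <- place_detectors_rect(p, 24, c("+y", "-y"))
r <- simulate_irradiation(p, b, d)
which.max(depth_dose_profile(r)) * 2   # Bragg depth, mm: 258
r$ledger$closure                       # energy ledger: 0.9991
```

The per-column currents rise toward the Bragg depth (the E⁻² scattering
signal) and vanish past it — downstream detectors see nothing because
end-of-range protons cannot leave the phantom.

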