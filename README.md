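# fdti

Simulation and analysis of **focal dynamic thermal imaging (FDTI)** — a
label-free photothermal technique in which a narrow, low-power 405 nm laser
beam briefly heats a small spot of tissue and a thermal camera records how
the induced surface temperature peak grows and relaxes.  Optical properties
(absorption µₐ, scattering µₛ, anisotropy g) set how much heat is deposited
and where; thermal properties (conductivity k, heat capacity ρc, perfusion
ω) set how it spreads.  Because tumors differ from healthy tissue in both —
elevated conductivity and stronger spatial heterogeneity — the shape of the
thermal peak carries diagnostic contrast that plain (static or widefield
dynamic) thermal imaging blurs away.

The package is written for researchers who want to simulate, prototype or
re-analyze FDTI-style experiments end to end:

* **Forward model** — explicit finite-difference solver for the Pennes
  bioheat equation,
  ρc ∂T/∂t = ∇·(k∇T) + ρ_b c_b ω (T_a − T) + Q_m + Q_laser,
  on voxelized heterogeneous samples, with harmonic-mean interface
  conductivities, radiative surface loss ε σ_SB (T⁴ − T⁴_amb), open
  far-field boundaries, and an attenuated Gaussian/top-hat beam source
  Q = µₐ Φ with Beer–Lambert depth attenuation µₜ' = µₐ + µₛ(1−g)
  (`step_heat()`, `equilibrate()`, `build_laser_source()`,
  `run_fdti_protocol()`), plus a thermal-camera model (area averaging,
  30 Hz, 0.02 K read noise).
* **Phantoms** — homogeneous baseline tissue and its parameter-sweep
  variants, ex vivo porcine fat/muscle, a 3D-printed pillar resolution
  target with ink-filled channels, and a seeded synthetic tumor/healthy
  cohort generator (`make_baseline()`, `make_porcine()`,
  `make_pillar_phantom()`, `make_cohort()`).
* **Feature battery** — ROI generation, peak amplitude/area/volume, FWHM by
  interpolated half-max crossings, 2D Gaussian and Lorentzian surface fits
  with SSE, steady-state dispersion, exponential rise/decay constants
  (`extract_features()` and friends).
* **Resolution analysis** — stepped-beam scanning (125 µm) with
  FWHM-vs-position profiles versus widefield per-pixel decay-constant
  mapping, under a common resolved-peak criterion (`scan_fdti()`,
  `decay_map()`, `count_resolved_peaks()`).
* **Classification** — Spearman feature ranking with t-tests,
  control-measurement normalization, correlation-matrix feature selection,
  and stratified fivefold cross-validated quadratic discriminant analysis
  with ROC/AUC (`rank_features()`, `normalize_to_control()`, `qda_cv()`,
  `multi_vs_single_feature()`).

## Worked example

Simulate one baseline FDTI acquisition (5 mW, 10 s exposure, 100 µm /
30 Hz camera) and extract its features:

```r
library(fdti)

mf    <- make_baseline()                    # 8 x 8 x 4 mm @ 100 um, Table-value tissue
video <- run_fdti_protocol(mf, laser_beam(), camera_model(noise_sd = 0),
                           sim_protocol())  # 2 min equilibration, 1 s pre, 10 s on, 10 s off
feats <- extract_features(video)
round(t(feats[, c("amplitude", "fwhm", "area", "volume",
                  "lor_sse", "gauss_sse", "tau_rise", "tau_decay")]), 3)
#> amplitude    1.539      # K of laser-induced excess at end of exposure
#> fwhm         1.681      # mm, mean of the x/y half-max widths
#> area         2.120      # mm^2 above half maximum
#> volume       6.217      # K mm^2 integrated excess
#> lor_sse      0.908      # the Lorentzian fits the conduction peak ...
#> gauss_sse    2.463      # ... better than the Gaussian, as expected
#> tau_rise     2.083      # s, exponential heating constant
#> tau_decay    3.852      # s, exponential recovery constant
```

A 5 mW beam raises the surface peak ~1.5 K; the spot is wider than the
0.69 × 1.35 mm beam because 10 s of conduction spreads it; the Lorentzian
SSE beats the Gaussian because conduction produces heavy-tailed peaks.

The full analyses live under `analysis/` as numbered drivers that write
their tables to `results/`:

```sh
Rscript analysis/01_parameter_sweep.R        # amplitude/FWHM vs k and mu_a
Rscript analysis/02_porcine_tissue.R         # fat vs muscle contrast
Rscript analysis/03_pillar_resolution.R      # scanned FDTI vs widefield DTI
Rscript analysis/04_cohort_classification.R  # tumor/healthy QDA pipeline
```

## Layout

```
R/                  package code (solver, phantoms, features, widefield, classification, IO)
src/                Rcpp core of the finite-difference solver
analysis/           numbered analysis drivers (thin wrappers over the package)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette: model, assumptions, design decisions
```
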