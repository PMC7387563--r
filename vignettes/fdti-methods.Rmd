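---
title: "Focal dynamic thermal imaging: model, features and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focal dynamic thermal imaging: model, features and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Focal dynamic thermal imaging (FDTI) probes a material by heating a small
spot with a low-power visible laser and watching, with a thermal camera, how
the induced surface temperature peak grows and relaxes.  Optical properties
(absorption, scattering) set how much heat is deposited and where; thermal
properties (conductivity, heat capacity, perfusion) set how it spreads.
This package provides the full computational counterpart of an FDTI study:
a bioheat forward simulator that doubles as the synthetic-data generator,
phantom builders, the thermal-video feature battery, a scanning-resolution
analysis against widefield dynamic thermal imaging (DTI), and the
statistical classification stage.  This vignette records the model, its
assumptions, the tunable parameters, and the design decisions a maintainer
would want to know.

## The forward model

### Pennes bioheat equation

Tissue temperature $T(\mathbf{x}, t)$ evolves as

$$\rho c \frac{\partial T}{\partial t} =
  \nabla \cdot (k \nabla T) + \rho_b c_b\, \omega\,(T_a - T) + Q_m + Q_{laser},$$

with tissue density $\rho$ (kg/m³), specific heat $c$ (J/(kg·K)),
conductivity $k$ (W/(m·K)), blood volumetric heat capacity $\rho_b c_b$
(J/(m³·K)), perfusion rate $\omega$ (1/s), arterial temperature $T_a$ (K),
metabolic heat $Q_m$ (W/m³) and the laser source $Q_{laser}$ (W/m³).  All
properties are per-voxel maps, so arbitrarily heterogeneous samples are
supported.  $\rho_b c_b$ defaults to the tissue's own $\rho c$ (the
parameter tables that define the study conditions list only tissue values)
and is configurable; $T_a$ defaults to the initial tissue temperature
(303.45 K for baseline tissue).

The solver (`step_heat()`) is explicit forward-Euler with a 7-point
conduction stencil.  Interface conductivities between voxels of differing
$k$ are harmonic means, which preserves flux continuity at material
boundaries — essential for the pillar phantom where $k$ jumps by a factor
of ~5 between polymer and ink.  The time step must satisfy the positivity
bound `stability_dt()`, $\mathrm{d}t \le \rho c / (\sum_f k_f/\Delta^2 +
\rho_b c_b \omega)$, which for a homogeneous medium is the familiar
$\rho c \Delta^2 / 6k$; violating steps are rejected by name, and the
default is 90% of the bound.  The explicit scheme was chosen over an
implicit one because the camera wants dense output anyway (30 Hz), the
stability-bounded step (~10 ms at 100 µm) is finer than the camera frame
interval, and the symmetric flux form conserves energy exactly (verified to
1e-6 relative over 1000 steps in the tests).

Boundaries: the imaged top surface loses heat radiatively as
$\varepsilon \sigma_{SB} (T^4 - T_{amb}^4)$ (no convection by default; a
convective coefficient is available and defaults to 0, since the modeled
surface is specified only by emissivity and ambient temperature).  Lateral
and bottom boundaries emulate "open" far-field tissue: during an
acquisition they are clamped one voxel outside the domain to the
equilibrated field (`boundary = "open"`), so heat flows out as if backed by
an infinite equilibrated medium.  The domain must therefore be chosen large
enough that the clamp sits several diffusion lengths
($\sqrt{4 \alpha t} \approx 2$ mm for 10 s in soft tissue) from the heated
spot; the defaults (8 × 8 × 4 mm around a ~1 mm beam) satisfy this.

### Laser source

The full radiative-transfer problem is replaced by an attenuated collimated
beam: surface irradiance is an elliptical Gaussian (FWHM 0.69 × 1.35 mm at
5 mW by default, matching the characterized instrument), integrated exactly
over each pixel by error-function differences, and attenuated in depth by
Beer–Lambert with the effective transport coefficient
$\mu_t' = \mu_a + \mu_s (1 - g)$.  The local source is the absorbed power,
$Q = \mu_a \Phi$, integrated exactly over each voxel layer so the volume
integral never exceeds the beam power.  The limitation is the absence of
lateral fluence spreading: scattered photons in reality blur the deposition
sideways by roughly a transport mean free path ($1/\mu_t' \approx 0.8$ mm
at baseline values).  At 405 nm absorption dominates the contrast the
method exploits, and the thermal point-spread over a 10 s exposure
(~2 mm) exceeds the optical blur, so trends are insensitive to this
approximation — but absolute FWHM values carry it as a systematic.
Specular reflection at the surface is ignored (all power enters; the
refractive index is retained as metadata only), consistent with treating
the nominal 5 mW as the power delivered into the tissue.

### Equilibration

Before each acquisition the sample self-regulates for 2 minutes without
laser (`equilibrate()`): perfusion and metabolism pull the bulk toward
$T_a + Q_m / (\rho_b c_b \omega)$ while the surface cools radiatively,
forming a millimetre-scale boundary layer.  For laterally homogeneous
fields the problem collapses by symmetry to one depth column, which is
solved and broadcast (exact for insulated lateral boundaries and orders of
magnitude cheaper); heterogeneous fields are stepped in 3D.  The residual
max $|\mathrm{d}T/\mathrm{d}t|$ is reported so callers can verify
near-steadiness (~3e-3 K/s after 120 s at baseline).  Note the perfusion
relaxation time $\rho c / (\rho_b c_b \omega) = 1000$ s exceeds the 2 min
protocol: equilibration reproduces the protocol's state, not the
asymptotic fixed point, which is why the solver oracle for the perfusion
steady state runs a dedicated long relaxation instead.

### Camera

`sample_camera()` area-averages simulation surface cells into camera
pixels (the camera pitch must be an integer multiple of the grid pitch;
the default grid spacing of 100 µm matches the instrument's pixel pitch
exactly), samples at the frame rate by snapping each nominal frame time to
the nearest solver step, and adds zero-mean Gaussian read noise with
σ = 0.02 K, the instrument's quoted sensitivity.  Noise is deterministic
given the protocol seed.  Optics (PSF, emissivity calibration) are out of
scope.

## Phantoms and the synthetic-data generator

`make_baseline()` and `make_porcine()` encode the two parameter tables
that define the study conditions (baseline/low/high sweep values; ex vivo
fat and muscle at 405 nm with perfusion and metabolism zeroed).

`make_pillar_phantom()` builds the resolution target: `n_pillars` polymer
stripes (1 mm wide, 1 mm apart by default), ink-filled channels between
and around them, over a solid polymer base.  Polymer and ink properties
are not published for the physical phantom, so literature-typical values
are used (polymer: k = 0.13 W/(m·K), ρ = 1240, c = 1800, µₐ = 5000 1/m —
an opaque black filament; ink at 1000× dilution: water thermal properties
k = 0.60, ρ = 1000, c = 4180, µₐ = 400 1/m).  The physical target was
filled with ink until the structure was visually obscured, so by default
the channels are over-filled: a thin ink film (`cover`, default 0.8 mm)
lies above the pillar tops.  This geometry is what produces the observed
contrast direction — the beam deposits heat in the same absorbing film
everywhere, and what differs is underneath: insulating polymer under a
pillar traps the heat, which then spreads laterally through the
high-diffusivity film into a *wide, tall* spot, while the water column
under a channel drains heat downward into a *narrow, short* spot.  With
the pillar tops flush at the surface (`cover = 0`) the ordering inverts,
because deep distributed absorption in the channels widens their surface
spots instead; both configurations are available.  All properties and the
fill height are config-exposed; the resolution analysis is geometric
(peak counting), not an absolute-temperature comparison.  Channel depth
(2 mm) and base thickness (1.2 mm) are likewise unpublished defaults.
The phantom is passive and starts at ambient temperature, so it is
already equilibrated.

`make_cohort()` is the tumor/healthy generator.  Healthy samples are
baseline tissue with a small per-sample multiplicative jitter (log-sd 3%)
of $k$ and $\mu_a$ — biological variability between measurement sites —
plus a mild radiometric surface mottle (below).  Tumor samples encode
three lesion contrasts, each chosen for the physical mechanism behind one
observed feature difference:

* **A large subsurface lesion with elevated conductivity** (+40%, radius
  4 mm, centre 2.5 mm deep; optionally several overlapping foci via
  `n_foci`): in the animal studies the whole probed site is tumor, and
  the elevated conductivity of cancerous tissue carries heat away from
  the spot faster, broadening the FWHM and flattening the peak.
* **Elevated absorption inside the lesion** (+70%): tumors recruit
  vasculature, and hemoglobin absorbs strongly at 405 nm near its Soret
  band.  This restores the peak amplitude that the conductivity elevation
  removes — without it, every dispersion statistic is dominated by the
  amplitude difference rather than by heterogeneity, inverting the
  observed direction of the steady-state std.
* **Heterogeneity at two scales.**  A bulk multiplicative log-normal
  Gaussian random field on $k$ (log-sd `heterogeneity/4`) and $\mu_a$
  (log-sd 0.08, correlation length 1.5 mm), each realized field
  normalized by its own spatial mean so the knob controls within-sample
  texture rather than a per-sample property lottery; and a *surface*
  radiometric mottle (`surface_gain`, tumor log-sd 0.05, healthy one
  fifth of that, correlation 0.5 mm), observed as
  $T_{amb} + g \odot (T - T_{amb})$.  The surface term is the dominant
  source of the Lorentzian-misfit and plateau-dispersion contrast, and
  deliberately so: ten seconds of lateral conduction smooths bulk
  property texture out of the surface temperature field almost entirely,
  while surface-level texture (scabby, vascular, irregular lesion skin)
  survives — which is also the only way to reconcile the in vivo
  observation that tumor peaks are *shorter and broader* yet have
  *higher* spatial dispersion.  Static offsets from the mottle are
  removed by background subtraction; what remains multiplies the excess.

A baseline temperature offset for tumors is available (rodent tumors run
cold) but defaults to 0 so that thermal-property contrast alone drives
classification.  What the generator does *not* emulate: resolved
vasculature, breathing/motion, skin layering, irregular lesion margins
beyond the multifocal option.  Passing tests therefore demonstrate that
the pipeline recovers the encoded contrast direction — not in vivo
performance, whose printed accuracy values are out of scope because the
animal recordings were never released.

## The feature battery

All features are measured on the background-subtracted ("excess") frame at
the end of the 10 s exposure, inside a square ROI (side = max(5 mm,
4 × beam FWHM)) centred on the hottest pixel of the lightly smoothed
excess near the user seed — locating the spot on the smoothed *excess*
rather than the raw frame means neither baseline structure nor a single
bright speckle (read noise, surface texture) can displace the ROI or set
a spiked half-maximum level, and the FWHM profiles then run through that
centre rather than re-snapping to the noisiest pixel.  Background is the
mean of all pre-laser frames, which maximally suppresses camera noise and
makes every feature invariant to constant temperature offsets:

* **Amplitude / Tmax** — peak excess and raw temperature.
* **FWHM** — half-maximum crossings linearly interpolated along each
  lateral axis through the peak; scalar FWHM is the mean of the two axis
  values (the beam is elliptical; the study reports a single FWHM without
  stating a reduction, so the mean is used and both axis values are kept).
* **Area** — pixel area × count of pixels above half amplitude (half-max
  support); **volume** — integral of positive excess.  Both are named but
  not defined in the source study; these definitions are the natural
  discrete ones and are validated against analytic surfaces
  (area → $\pi\gamma^2$ for a Lorentzian, volume → $2\pi A \sigma^2$ for a
  Gaussian).
* **2D Gaussian and Lorentzian fits** — Levenberg–Marquardt least squares
  with centres bounded inside the ROI and widths in (0.1 px, ROI extent)
  to exclude degenerate flat fits; initialized from the peak metrics and
  FWHM.  Non-convergence is flagged, never thrown; a zero-residual start
  is treated as converged.  SSE is reported raw (K², matching the study's
  classification input) plus per-pixel MSE for cross-ROI comparability.
* **Steady-state std** — the study's wording is ambiguous between spatial
  and temporal dispersion; the spatial reading (std across ROI pixels of
  the excess frame averaged over the last 1 s of exposure) is primary,
  since heterogeneity roughens the plateau *surface*; the temporal
  variant is reported as a secondary column.
* **Rise/decay constants** — the peak-pixel excess time course fitted to
  $A(1 - e^{-t/\tau})$ during exposure and $B e^{-t/\tau}$ after, with
  $R^2$ reported and non-positive constants flagged.

FWHM is measured on background-subtracted temperature (the source study
does not say raw vs subtracted); subtraction is the defensible choice
because the equilibrated field is not flat (radiative surface cooling).

## Resolution analysis

`scan_fdti()` steps the beam across the pillars in 125 µm steps.  For
scanning, the pinhole-conditioned beam is modeled as a 1 mm flat-top
("tophat") disc rather than a Gaussian: a pinhole truncates the profile,
and the Gaussian's tails otherwise deposit heat on both structures
flanking the target stripe, blurring exactly the contrast the scan is
meant to resolve.  (Diffraction detail of the pinhole is invisible at the
100 µm grid.)  The scan resets the sample to the laser-free equilibrated state
between positions (exact re-equilibration, since laser-free relaxation is
deterministic).  The FWHM-vs-position profile is the resolution readout.
`decay_map()` implements the widefield comparison: per-pixel exponential
decay constants after a 1 cm flat-top LED exposure, fitted log-linearly
(least squares on log excess — fast enough for thousands of pixels and
exact for clean exponentials), with sub-noise-floor pixels flagged
invalid.

The resolved-peak criterion (`count_resolved_peaks()`) is not defined in
the source study, which reports "three distinct peaks" qualitatively: a
peak here is a local maximum with topographic prominence at least 20% of
the profile's dynamic range, separated from taller accepted peaks by at
least half the expected 2 mm pitch, counted after a 3-sample moving
average (so a single noisy sample cannot masquerade as structure; the
2 mm pitch spans 16 scan samples, so the smoothing cannot merge real
peaks).  Both readouts pass through the identical criterion; the headline property is that scanning resolves the
three pillars while the widefield transect does not.

## Classification stage

`rank_features()` ranks by |Spearman ρ| against the binary label with
Welch t-tests at α = 0.05 (a paired option exists; the source study does
not state pairing, so unpaired is the default).  `normalize_to_control()`
implements the temperature-matched-control design (every feature divided
by the subject's designated control measurement); the contralateral
design uses unnormalized features.  `qda_cv()` fits per-class-covariance
Gaussian discriminants under stratified fivefold cross-validation (seeded
and therefore reproducible; stratification keeps class ratios within one
sample per fold, which matters at n = 9), pools out-of-fold posterior
probabilities, and computes ROC/AUC with a fixed score direction so that
permuted-label nulls are unbiased at AUC 0.5.  Grouped fold assignment
(all measurements of an animal in one fold) is available to prevent
leakage with repeated measures and is the recommended unit; ungrouped
assignment reproduces the per-measurement reading.  Singular class
covariances fall back to a ridge-regularized discriminant
(ε = 10⁻⁶ · trace/d) and are flagged.

## Numerical choices and problem sizes

Chosen once, as the package's own defaults:

* Grid spacing 100 µm (matches camera pitch) for the sweep, porcine and
  pillar scenarios; domain 8 × 8 × 4 mm for single-spot runs; the pillar
  domain spans the pillar block plus 2.5 mm ink margins laterally and
  12 mm along the stripes so the 1 cm widefield spot fits.
* The cohort study runs at 200 µm spacing on 8 × 8 × 4 mm (40 × 40 × 20
  voxels), 20 samples per arm, five independent cohorts: a halved grid
  resolution is ample for ~2 mm-wide peaks, and 100 samples per arm gives
  the pooled t-tests their power.
* Solver step: 90% of the stability bound; camera 30 Hz; 2 min
  equilibration, 1 s pre-laser, 10 s exposure, 10 s decay (5 s decay
  during scans, where the profile readout is the end-of-exposure FWHM).
* Grid convergence: halving the spacing on the baseline scenario moves
  the camera-observed peak excess by under 10% (tested); trend and
  peak-counting results are asserted only at fixed grids.
* Tolerances: heat-kernel oracle < 2% relative L2; perfusion steady state
  < 1%; conservation 1e-6 relative; analytic feature values at
  interpolation/optimizer tolerance.

## Known limitations

* No lateral fluence spreading (collimated Beer–Lambert beam), no Fresnel
  loss, no participating-media re-emission.
* Fourier conduction only; no non-Fourier effects, motion, or breathing.
* The camera model is pitch-aligned area averaging plus white noise; no
  PSF, no emissivity miscalibration, no fixed-pattern noise.
* The cohort generator encodes two tumor contrasts (bulk conductivity,
  spatial heterogeneity); real tumors differ in more ways, and the
  in vivo accuracy printed in the source study is deliberately not a
  target of this package.
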