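# dcedot

Simulation and reconstruction for **dynamic contrast-enhanced diffuse
optical tomography (DCE-DOT)** on arbitrarily shaped 2-D phantoms, with
and without MRI-derived structural priors.

Diffuse optical tomography recovers tissue absorption (µa) and reduced
scattering (µs′) from near-infrared boundary measurements, but the inverse
problem is severely ill-posed: small lesions are barely visible, and the
images are contaminated by modelling mismatch and per-fibre coupling
errors. Two remedies are studied here together: *contrast enhancement*
(inject an NIR absorber such as indocyanine green and subtract a baseline
reconstruction, so only the change matters) and *anatomical priors* (use
the lesion region from a coregistered MR image to regularize the
inversion). `dcedot` implements the full computational chain needed to
compare these strategies quantitatively — for people developing DOT
reconstruction methods, multimodal MRI-DOT systems, or optical
contrast-agent imaging protocols.

## What is inside

* **Forward model** — frequency-domain diffusion equation
  `∇·(D∇Φ) − (µa + iω/c_n)Φ = −q0` with Robin boundary condition
  `Φ + 2AD ∂Φ/∂n = 0`, solved by linear-triangle FEM (complex symmetric
  sparse system, one factorisation per 8-source frame); boundary flux
  `φ = Φ/(2A)`, 64 amplitude + 64 phase data per frame from an
  8-source/8-detector fan-beam layout. Validated against the 2-D
  infinite-medium Green's function `K0(kr)/(2πD)`.
* **Geometry pipeline** — MR-like binary masks of eight programmatic
  phantom shapes, half-maximum thresholding, boundary tracing and
  decimation, Delaunay meshing, fan-beam optode mapping at 22.5° spacing.
* **Inversion** — Levenberg–Marquardt updates
  `X ← X + (JᵀJ + λR)⁻¹Jᵀε` with an adjoint-method Jacobian, in four
  analysis methods: (1) amplitude+phase for µa and µs′; (2) amplitude-only
  for µa; (3) method 2 with explicit per-optode coupling gains; (4) method
  2 with the Laplacian region prior `R = LᵀL` built from the MR mask.
  Homogeneous-phantom calibration
  `F_cal = F_meas / F_homo_meas × F_homo_forw` and a global two-parameter
  homogeneous fit.
* **DCE analysis** — enhancement difference images, FWHM or prior ROIs,
  enhancement-vs-contrast linearity (slope, intercept,
  `|data − fit|/max(data)` deviations), ICG kinetics curves with
  max-normalisation.
* **Synthetic data** — the B0–B8 contrast series (background µa = 0.01,
  µs′ = 0.6 mm⁻¹; inclusion µa up to 0.08 mm⁻¹), the homogeneous
  calibration phantom (µa = 0.006, µs′ = 1.0 mm⁻¹), seeded amplitude/phase
  noise, coupling corruption, and a 32-frame gamma-variate ICG series with
  injection during frame 7 at 16 s resolution — all with exact ground
  truth attached.

The `analysis/` scripts run the two end-to-end studies
(`01_phantom_study.R`: 8 shapes × 5 contrasts × 4 methods;
`02_icg_study.R`: 32-frame kinetics with methods 2 and 4;
`03_report.R`: markdown summary from the saved tables).

## Worked example

Simulate the highest-contrast phantom, calibrate, reconstruct with the
structural prior, and quantify the enhancement:

```r
library(dcedot)

## geometry: a 25 mm-radius circular phantom with a 10 mm inclusion at (8, 0)
shape  <- make_shape("circle", scale = 25)
mesh   <- build_mesh(shape$polygon, target_edge_mm = 2.8)
mesh   <- label_region(mesh, disk_polygon(c(8, 0), diameter = 10))
layout <- map_optodes(mesh)
cfg    <- forward_config()
mesh
#> dot_mesh: 340 nodes, 582 elements, 96 boundary edges, 2 region(s)

## B-series ground truth and simulated, calibrated measurements
spec   <- phantom_spec(shape$polygon, inclusion_center = c(8, 0))
series <- make_phantom_series(spec, mesh)
homo   <- forward_measurements(mesh, make_calibration_phantom(mesh), layout, cfg)
frames <- lapply(series, simulate_measurements, layout = layout,
                 noise = noise_model(amplitude_cv = 0.01, seed = 1), cfg = cfg)
calib  <- lapply(frames, calibrate, homo_measured = homo, homo_forward = homo)
calib$B8
#> dot_frame: 8 x 8 source-detector pairs (64 amplitude + 64 phase), t = 0 s

## reconstruct baseline (B0) and B8 with the structural prior (method 4)
hom  <- fit_homogeneous(calib$B0, mesh, layout, cfg)
rec0 <- reconstruct(calib$B0, mesh, layout, 4, cfg, control = list(homog = hom))
rec8 <- reconstruct(calib$B8, mesh, layout, 4, cfg, control = list(homog = hom))
rec8
#> dot_recon (method 4): 20 iterations, objective 14.9 -> 0.00062

## enhancement image and ROI mean
enh <- difference_map(rec8$map, rec0$map, label = "B8 - B0")
enh
#> enhancement_map (B8 - B0): 340 nodes, range [-0.00697, 0.0729] mm^-1
mean_enhancement(enh, roi_from_prior(mesh, 1))
#> [1] 0.07114
```

The inclusion's true enhancement is 0.07 mm⁻¹ (µa 0.08 post vs 0.01
pre-contrast); the prior-guided reconstruction recovers a mean ROI
enhancement of 0.0711 mm⁻¹ under 1 % amplitude noise. The same pipeline
with methods 1–3 underestimates the inclusion and shows the
enhancement-linearity deviations that the phantom study quantifies.

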