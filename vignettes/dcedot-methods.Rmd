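---
title: "Models and methods behind dcedot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dcedot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dcedot` simulates and analyses dynamic contrast-enhanced diffuse optical
tomography (DCE-DOT) experiments on arbitrarily shaped two-dimensional
phantoms.  This vignette documents the physical model, the inverse solver,
the synthetic-data generator and the numerical choices, so that every
number the package produces can be traced to a stated assumption.

## Forward model

Light transport is modelled by the frequency-domain diffusion equation on a
2-D domain,

$$\nabla \cdot [D(\mathbf r)\,\nabla \Phi(\mathbf r,\omega)]
  - \Big[\mu_a(\mathbf r) + \tfrac{i\omega}{c_n}\Big]\,\Phi(\mathbf r,\omega)
  = -q_0(\mathbf r,\omega),$$

with fluence rate $\Phi$, absorption $\mu_a$ (mm$^{-1}$), reduced
scattering $\mu_s'$ (mm$^{-1}$) and diffusion coefficient
$D = 1/[3(\mu_a+\mu_s')]$ (mm).  The Robin boundary condition
$\Phi + 2AD\,\partial\Phi/\partial n = 0$ closes the problem; the
measurable boundary flux is $\phi = \Phi/(2A)$ at the detector node.  A 2-D
model is used because the imaging task is a single transverse slice; the
2-D infinite-medium Green's function $\Phi(r) = K_0(kr)/(2\pi D)$ with
$k^2 = (\mu_a + i\omega/c_n)/D$ serves as the analytic oracle for the
solver (the test suite checks 5 % amplitude / 2 degree phase agreement at
mid-radius of a large disk).

Discretisation is by linear triangular finite elements.  The stiffness term
uses the element-mean diffusion coefficient (exact for linear $D$ per
element), the absorption mass term uses the exact integrals of products of
three linear shape functions, and the Robin term is a boundary-edge mass
matrix weighted by $1/(2A)$.  The assembled system is complex symmetric;
it is solved through a sparse LU factorisation of its real $2N \times 2N$
block form, factored once per frame and reused for all 8 sources and all
8 adjoint (detector) solves.

Key parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `modulation_freq` | 100 MHz | source intensity modulation |
| `n_interior` | 1.4 | tissue-like refractive index |
| `A` | derived, ≈ 3.25 | boundary mismatch, from the effective-reflection polynomial $R_\mathrm{eff}(n)$, $A=(1+R_\mathrm{eff})/(1-R_\mathrm{eff})$; overridable |
| `c0` | $2.998\times10^{11}$ mm/s | vacuum light speed; $\omega/c_n$ then has units mm$^{-1}$ |

The point source of an optode is placed one transport length $1/\mu_s'$
inside the boundary along the inward normal and distributed onto the
enclosing element with barycentric weights.  Phase is reported with the
$e^{+i\omega t}$ convention as a positive lag, $-\mathrm{Arg}\,\phi$,
unwrapped along the detector index within each source.  The absolute
source scale is irrelevant after calibration (below).

Because $A$ cancels through the calibration ratio, the exact value of the
effective-reflection approximation does not propagate into reconstructed
images; it only sets the absolute scale of simulated raw data.

## Geometry pipeline

Phantom geometry enters as an MR-like binary mask.  The pipeline mirrors
how a coregistered MR slice would be processed: threshold at half the
maximum intensity and keep the largest connected component
(`mask_from_image`), trace the exterior boundary pixels and keep one of
every five (`extract_boundary`, pixel size 0.5 mm/pixel by default),
triangulate the polygon (`build_mesh`, Delaunay triangulation of the
boundary vertices plus an interior hexagonal lattice, clipped to the
polygon), and cast 16 rays at 22.5 degree increments from a user-supplied
centre to place 8 sources and 8 detectors on boundary nodes
(`map_optodes`).  Fiducial-based MR coregistration has no meaning for
synthetic data, so the ray centre is supplied directly (the origin for the
catalogue shapes).  Indices are 1-based throughout, as is idiomatic in R;
the mesh text files and CSV outputs carry 1-based indices.

The eight phantom shapes (`shape_ids()`) are defined by star-shaped radial
functions (circle, ellipse, bean, trilobe, pear, peanut, D-shape, and a
low-order Fourier blob).  They stand in for agar phantoms whose true
outlines are only available as images; defining them analytically gives
exact geometric ground truth, at the cost of not reproducing any
particular physical phantom.  A structured polar mesh
(`polar_disk_mesh`) complements the unstructured mesher for validation:
its rings carry multiples of 16 nodes so every optode angle is an exact
node at every refinement level, which is what makes the rotational
symmetry check (equal source-detector separations agree to $10^{-6}$) and
the grid-convergence check (log-amplitude changes < 1 % when the edge
length is halved) meaningful; optode snapping on unstructured meshes
would otherwise dominate both.  A `mirror_symmetric` variant reflects an
upper-half triangulation for mirror-image checks.

## Calibration

Measured data are calibrated against a homogeneous reference phantom
($\mu_a = 0.006$, $\mu_s' = 1.0$ mm$^{-1}$) by the element-wise complex
ratio

$$F_\mathrm{calibrated} =
  \frac{F_\mathrm{measured}}{F_\mathrm{homo\_measured}}\times
  F_\mathrm{homo\_forw},$$

which removes multiplicative instrument factors common to the object and
reference scans and, because the reference numerator is simulated on the
data-generation mesh while $F_\mathrm{homo\_forw}$ is computed on the
reconstruction mesh, also cancels discretisation mismatch to first order.
In the simulated studies the reference scan is generated noise-free and
with unit coupling: the couplings handled by analysis method 3 represent
contact-variability *drift* between the reference scan and the object
scan, which is exactly the component the ratio cannot remove.

## Inverse problem

The reconstruction minimises the sum of squared residuals between measured
and predicted data.  Residuals are stacked in log-amplitude and phase
space rather than raw complex values: the data span several decades of
dynamic range, the multiplicative calibration is additive in log space,
and phase residuals can be formed as wrapped differences, immune to
unwrapping conventions.  The damped update is

$$X_{m+1} = X_m + (J^TJ + \lambda R)^{-1} J^T \varepsilon,$$

with $R = I$ (methods 1–3) or $R = L^TL$ (method 4).  The Jacobian is
computed by the adjoint method: one factorisation yields the 8 forward and
8 adjoint fields, and the sensitivity of each datum to each nodal unknown
is assembled element-wise, including both the direct absorption (mass)
term and the $\partial D/\partial\mu_a = -3D^2$ stiffness term.  The test
suite checks the adjoint Jacobian against central finite differences to a
relative error below $10^{-3}$ (it agrees to ~$10^{-9}$); the only
deliberately omitted dependence is the source-placement depth $1/\mu_s'$,
whose variation with the local scattering estimate is a negligible,
non-standard term.

Choices the damping schedule needed (no values are stated in the
literature the model follows): $\lambda_0 = 10\,\mathrm{mean\,diag}(J^TJ)$,
halved on each accepted step, multiplied by 10 on rejection (up to 8
escalations), stopping after 20 iterations or when the objective changes
by less than $10^{-3}$ relative.  Accepted steps never increase the
objective.  Absorption updates are floored at $10^{-4}$ mm$^{-1}$
(positivity; prevents the diffusion coefficient from blowing up),
scattering at 0.05 mm$^{-1}$.

### The four analysis methods

1. **Amplitude + phase, $\mu_a$ and $\mu_s'$** — 128 data, $2N$ unknowns,
   identity damping.
2. **Amplitude only, $\mu_a$** — 64 log-amplitude data; $\mu_s'$ fixed at
   the global homogeneous fit (`fit_homogeneous`, a two-parameter
   Levenberg–Marquardt fit on log-parameters against both amplitude and
   phase).  This is the continuous-wave-equivalent analysis.
3. **Method 2 + source/detector couplings** — the measured amplitude for
   pair $(i,j)$ is modelled as $s_i d_j$ times the predicted flux.  In log
   space the 16 gains are *linear* unknowns, so each iteration refreshes
   them with their exact least-squares values (the row/column means of the
   log-amplitude residual; separable least squares) under the zero-sum
   gauge $\sum \log s_i = \sum \log d_j = 0$, before the damped $\mu_a$
   step.  A joint damped step over $(\mu_a, \log s, \log d)$ was tried
   first and rejected: the nodal damping scale buries the 16 gain columns
   and an injected gain is recovered only fractionally.  The zero-sum
   gauge means the gains absorb only differential per-optode effects; the
   overall scale stays with the image.  With 64 amplitude data the gains
   and near-optode absorption share a genuinely degenerate subspace, so
   modelling the couplings slightly reduces the recovered contrast — the
   expected behaviour of decoupling estimators — while suppressing the
   hypersensitive spots at the optode positions.
4. **Method 2 + Laplacian structural prior** — the damping matrix becomes
   $L^TL$ with $L_{ii} = 1$, $L_{ij} = -1/N_r$ for nodes sharing a region
   of $N_r$ nodes, 0 across regions.  $Lv$ vanishes on region-wise
   constant vectors, so the penalty suppresses within-region variation
   while leaving region offsets essentially free.  The off-diagonal sign
   is negative; with a positive sign the matrix would penalise the region
   mean itself rather than deviations from it (a flag `printed_sign`
   builds that variant for comparison).  Region labels come from the
   MR-like mask geometry (`label_region`).

## Synthetic-data generator

The generator produces every input with known ground truth:

* **Contrast series**: background $\mu_a = 0.01$, $\mu_s' = 0.6$
  mm$^{-1}$; a 10 mm inclusion at object-to-background contrasts
  1, 2, 4, 6, 8 ($\mu_a$ = 0.01 … 0.08 mm$^{-1}$), the B0–B8 series.  The
  B0 frame is the pre-injection baseline for all difference images.
* **Noise**: multiplicative Gaussian on amplitude (default 1 %), additive
  Gaussian on phase (default 0.1 degree) — the conventional
  frequency-domain instrument model; no instrument noise figures are
  stated in the source material, so these are chosen as typical of
  photomultiplier-based systems.  All noise is seeded and bit-reproducible,
  and the generator restores the caller's RNG state.
* **Couplings**: per-optode multiplicative gains applied to object frames
  only (drift relative to the calibration scan).
* **ICG kinetics**: a gamma-variate bolus response,
  $(\tau/t_r)^{\alpha} e^{\alpha(1-\tau/t_r)}$ with
  $\alpha = t_r/t_d$, scaled to a peak enhancement of 0.03 mm$^{-1}$ in
  the inclusion, with rise time $t_r = 48$ s and decay time $t_d = 120$ s
  — a bolus that peaks ~3 frames after injection and washes out over a few
  minutes, the shape reported for ICG in small-animal imaging.  The series
  has 32 frames at 16 s resolution with injection during frame 7; frames
  1–6 are bit-exactly baseline.  The background receives 10 % of the
  inclusion curve so difference images have realistic non-zero
  backgrounds.

The data-generation mesh is by default 1.5× finer than the reconstruction
mesh, so recovery tests do not commit the inverse crime; a `same_mesh`
flag enables the model-consistent configuration used for exact-recovery
checks.  The homogeneous-fit recovery checks (background and calibration
media within 2 %) use the model-consistent configuration deliberately:
they verify the fitting machinery, and at practical mesh resolutions the
pure discretisation difference between a 3 mm and a 2 mm mesh already
accounts for ~2 % in the fitted coefficients, which would conflate solver
and discretisation error.

What the generator does *not* emulate: 3-D light propagation, real MR
intensity distributions (masks are exact geometric rasters), physiological
noise or motion, wavelength dependence, and fluorescence.  Passing tests
demonstrate internal consistency of the solver chain and the comparative
behaviour of the analysis methods under the stated noise model — not
instrument-level accuracy on real tissue.

## DCE analysis

Enhancement maps are node-wise differences of reconstructions
(`difference_map`, post − pre).  ROIs are either the half-maximum set of
the enhancement map restricted to the connected component containing the
peak (`roi_fwhm`; the background level is the node median — robust against
the inclusion's own nodes — and connectivity is element adjacency), or the
structural prior region (`roi_from_prior`).  For methods 1–3 the ROI is
taken from the top-contrast enhancement map and then applied to all
contrasts of that method, which keeps low-contrast cells well-defined even
when their own maps are noise-dominated.  Region means are area-weighted
(node weight = one third of incident element areas) so they are stable
under refinement.  Linearity of mean enhancement versus contrast is
summarised by an ordinary least-squares line and the deviation vector
$|y - \hat y| / \max(y)$; kinetics curves are per-frame ROI means with a
max-normalised variant.

## Study drivers and problem sizes

`run_phantom_study()` and `run_dce_study()` execute the two end-to-end
experiments from one `experiment_config()`; the scripts under `analysis/`
are thin drivers around them.  Default desk scales: reconstruction meshes
of a few hundred nodes (3 mm target edge on 25 mm-radius phantoms,
~1.5× finer data meshes), which resolve the 10 mm inclusion with 10–15
nodes and keep a full 8-shape × 5-contrast × 4-method study plus a
32-frame kinetics study in the tens of minutes on one core.  The test
suite uses the same drivers at slightly coarser settings.  All stochastic
steps derive per-frame seeds from one master seed; rerunning a
configuration reproduces every table bit-exactly.

## Known limitations

* 2-D only; out-of-plane light loss is not modelled, so absolute recovered
  values are not transferable to 3-D experiments.
* Single mesh per reconstruction (no dual coarse/fine basis); mesh
  resolution is the only resolution control.
* Method 1's simultaneous $(\mu_a, \mu_s')$ inversion uses plain identity
  damping; no cross-parameter scaling is applied, which is adequate at
  these noise levels but not optimal.
* The coupling model estimates amplitude gains only; phase coupling is not
  estimated (methods 2–4 use amplitude data only).
* No pharmacokinetic compartment modelling: the kinetics analysis stops at
  enhancement curves by design.
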