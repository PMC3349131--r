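---
title: "Discrete-vessel bioheat modelling of focused-ultrasound treatments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-vessel bioheat modelling of focused-ultrasound treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`fusbioheat` simulates the temperature and thermal-dose field produced by a
focused-ultrasound (FUS) source in a homogeneous block of muscle-like tissue
containing discrete, thermally significant blood vessels. Vessels with
diameters of roughly 0.2–0.8 mm are too large for their effect to be absorbed
into a volumetric perfusion sink (the Pennes picture) and too small to appear
in routine angiography: blood passing through them does not equilibrate with
the surrounding tissue, so each one locally depresses the temperature field
and must be modelled as a geometric object.

The package follows the two-domain formulation. In tissue, conduction with an
*enhanced* effective conductivity (which absorbs the mixing effect of the
smallest, unresolved vessels):

$$\rho_t c_{pt} \frac{\partial T}{\partial t}
  = \nabla\!\cdot\!(k_{\mathrm{eff}}\nabla T) + P_{\mathrm{FUS}},$$

and inside each straight cylindrical lumen, conduction plus axial convection
with a Poiseuille (parabolic) profile:

$$\rho_b c_{pb} \frac{\partial T}{\partial t}
  = \nabla\!\cdot\!(k_b\nabla T) - \rho_b c_{pb}\, w\,
    \frac{\partial T}{\partial z} + P_{\mathrm{FUS}},
  \qquad w(r) = 2 V_m \left(1 - \frac{r^2}{R^2}\right).$$

No wall heat-transfer coefficient is imposed: the two domains share one
temperature field and flux continuity at the wall is enforced by the
discretization (harmonic-mean face conductivity), so the effective Nusselt
number emerges from the solution.

The deposited power is a separable Gaussian,
$P = P_0 \prod_u \exp(-\ln 2\, u^2/R_u^2)$, parameterized by its half-power
width and height. We read "half-power width" as a *full* width at half
maximum, so $R_u = \mathrm{FWHM}/2$ and the deposition falls to $P_0/2$ one
half-width from the focus. The alternative reading ($R_u$ equal to the full
width) doubles every beam dimension; with the canonical single-artery source
(4 mm / 30 mm, 15 W cm$^{-3}$) it predicts a 60 s no-vessel focal rise near
80 °C, far above the ~30 °C scale reported for such exposures, while the
FWHM reading gives ~34 °C. The switch is the `fwhm_*` arguments of
`fus_source()`, so the other convention is one constructor call away.

Thermal damage is quantified as cumulative equivalent minutes at 43 °C
(CEM43): $TD = \int \mathcal{R}^{43 - T(t')}\,dt'$ with $\mathcal{R} = 0.5$
at or above 43 °C and $0.25$ below, normalized by the 240 eq-min threshold
conventionally taken as 100 % necrosis in muscle.

Boundary conditions: tissue faces couple to the 37 °C body core through a
Robin coefficient $h = k_{\mathrm{eff}}/d$, representing a layer of tissue of
thickness $d$ between the block and the core ($d$ defaults to 20 mm,
i.e. "a few centimetres", and is configurable); vessel inlets are held at the
core temperature; vessel outlets carry a pure advective outflow (zero
diffusive flux). The initial temperature is 37 °C everywhere.

## Discretization

The solver is a cell-centred finite-volume scheme on a uniform Cartesian
grid (or an $(r,z)$ axisymmetric grid when a single vessel is coaxial with
the beam; the $r=0$ face has zero area, which enforces the symmetry
condition naturally). Each time step applies backward-Euler,
locally-one-dimensional sweeps — one tridiagonal solve per axis, with
first-order upwind advection folded into the axis it acts along — followed
by the source term, split symmetrically (half before, half after the
sweeps), and the CEM43 update on end-of-step temperatures. Because the
coefficients are constant in time, the Thomas-algorithm factors are built
once per run and each step reduces to forward/backward substitutions,
implemented in C++. All sweeps are unconditionally stable and monotone, so
the scheme satisfies a discrete maximum principle; an explicit forward-Euler
reference stepper (with a checked stability bound) and a plain-R replica of
the implicit sweeps exist for cross-validation, and a per-step energy ledger
(storage = source − boundary losses − advective outflow, exact to round-off
for the implicit scheme) is verified in the test suite.

The solver was validated against closed forms: 1-D and 3-D heat-kernel
releases match the analytic Gaussian kernel to within 2 % in L2 at
0.2 mm / 0.05 s; a warm slug in a lumen column translates at the local
parabolic speed with conserved heat content; constant-temperature CEM43
doses are exact; and axisymmetric and full-3-D runs of the centred large
artery agree to within 2 % on the peak rise.

## Numerical choices and their error

Two discretization scales matter and pull in opposite directions:

* **Transverse resolution at vessel walls.** The conjugate tissue–lumen
  exchange develops a thin boundary layer; an axisymmetric refinement study
  of the large artery (R = 1.5 mm) shows the 60 s wall rise climbing from
  2.9 °C at 0.5 mm to 6.4 °C at 0.125 mm spacing. Coarse grids therefore
  *overestimate* vessel cooling. Because the vessels and the beam are both
  axial while axial gradients are gentle (beam half-power heights of
  24–30 mm), the package uses anisotropic grids: fine transverse spacing
  (0.2–0.3 mm, at least two nodes per vessel radius) with 1–2 mm axial
  spacing, which a sensitivity study shows changes midplane peaks by under
  1 %.
* **Time step near vessels.** Blood traverses the heated region in well
  under a second, so at practical `dt` the implicit upwind advection
  operates far above CFL 1. This is stable and recovers the quasi-steady
  cold-lumen limit, but the splitting against conduction leaves a
  first-order `dt` error concentrated near lumens: a vessel-adjacent focal
  peak moves by about 4 % between `dt` = 0.1 s and 0.05 s (under 0.5 % away
  from vessels). Treatment simulations use `dt` = 0.1 s as the
  accuracy/cost balance; the single-insonation default is 0.05 s.

Desk-scale problem sizes used by the analyses, tests and the acceptance
script: treatments of the multi-pair block run on a
0.2 × 0.2 × 2 mm grid (105 × 105 × 13 cells) at `dt` = 0.1 s; the
counterflow-pair comparison uses 0.3 × 0.3 × 1 mm over the
60 × 60 × 40 mm³ block. These sizes were chosen from the convergence
studies above — the reported quantities change by a few per cent, not
qualitatively, under refinement.

Dose accumulation in the compiled stepper skips nodes below 38 °C
(configurable `dose_cutoff`); the neglected rate is at most $0.25^5 \approx
10^{-3}$ eq-min per minute, i.e. below $10^{-4}$ normalized dose over a full
23-minute treatment. The exported `accumulate_dose()` applies no cutoff.
The rectangle rule on end-of-step temperatures tracks a 1000× finer
quadrature within 0.5 % on linear ramps at the 0.05 s cadence.

## Scenarios as synthetic data

All study inputs are parametric, so the "data generator" is the scenario
module. The canonical configurations are:

* single straight arteries targeted on-axis — large (R = 1.5 mm, L = 200 mm,
  $V_m$ = 13 cm/s), primary (0.5 mm / 100 mm / 8 cm/s) and secondary
  (0.3 mm / 40 mm / 8 cm/s) calibres, solvable axisymmetrically;
* the large artery in a 60 × 60 × 40 mm³ block with an off-wall focus or a
  tilted axis (full 3-D);
* a counterflow pair: two large-artery vessels with antiparallel flow, walls
  1 mm either side of the central focus;
* the multi-pair treatment block: 21 × 21 × 26 mm³ with three artery–vein
  pairs of radius 0.5 mm (wall-to-wall gap 0.8 mm) and six of radius 0.4 mm
  (gap 0.6 mm), all axial.

Where the underlying description is silent the package fixes a value once
and exposes it as an argument: the multi-pair in-plane layout is the
versioned constant `multipair_layout()` (large pairs on the midline at
x = −6, 0, +6 mm; small pairs interleaved at x = ±3, ±6, ±9 mm with
alternating y = ±4 mm, all inside the 14 × 12 mm insonation footprint, the
arrangement that puts every pair where treatment dose maps show their
underdosage rings);
the pair separations are read wall-to-wall, since centre-to-centre values of
0.8 mm would make 1 mm-diameter lumens overlap; vein velocities equal artery
velocities (8 cm/s) for want of stated values; the boundary-layer thickness
is d = 20 mm; transverse extents of the axisymmetric domains default to a
30 mm radius. What the generator deliberately does *not* emulate: curved or
branching vasculature, pulsatile or temperature-dependent flow,
heterogeneous acoustic/thermal properties, and physical acoustics
(diffraction, attenuation, nonlinearity) — the deposition shape is
prescribed, not propagated. Passing tests therefore validate the coupled
conduction–convection–dose machinery under idealized vascular geometry, not
patient realism.

## Treatment delivery and the power controller

A treatment is 56 insonations of 20 s, each followed by 5 s of cooling
(none after the last; 1395 s in total), with foci on a 2 mm-pitch grid in
the transverse midplane. Delivery orders: a row-major raster from the
top-left; a seeded random order constrained so consecutive foci are at
least 8 mm apart (rejection resampling of greedy draws, up to 10,000
restarts); and an outward Archimedean spiral with 2 mm turn spacing and
2 mm arc-length stepping.

Variable-power delivery emulates feedback control: each event's power is
chosen so its peak incremental midplane dose lands in 230–250 eq-min, just
below the necrosis threshold. The reference procedure adjusted power by
hand; the package automates it reproducibly. Because the governing
equations are linear in the deposited power, the event is pre-simulated
twice from the checkpointed state — once freely decaying, once at a
reference power — and the midplane temperature history for *any* power
follows by superposition; `control_power()` then runs a secant search on
log-dose (dose is strictly monotone in power), capped at 8 iterations, and
the accepted power is committed in a final full simulation that accumulates
dose. Per-event dose evaluations cost milliseconds, so the search is exact
for practical purposes rather than a two-to-three-step manual
approximation.

Midplane dose statistics mask voxels at or below 0.3 normalized dose to
exclude the cool vessel interiors, and use the population SD (the voxel set
is the whole population of the plane; with thousands of voxels the
sample/population distinction is negligible, and `dose_stats()` exposes the
choice).

## Known limitations

* Fixed-power dose statistics are extremely sensitive to the model's
  thermal gain: CEM43 doubles per extra degree, so a ~10–20 % difference in
  peak rise — well within the spread expected between discretizations,
  meshes and layout choices for this problem — moves masked dose means by
  factors of 2–100 in the sequential and spiral cases, where 2 mm-spaced
  neighbours compound the build-up. Dose-capped results are robust
  (the controller absorbs gain differences), which is the central point of
  the study design. Comparisons of fixed-power dose magnitudes against
  external references should be read with that sensitivity in mind.
* Coarse transverse grids overestimate vessel cooling (boundary-layer
  under-resolution); the counterflow-pair reduction stabilizes near 60 %
  under refinement of this implementation, and that figure inherits the
  idealized geometry (infinite straight vessels spanning the heated
  column).
* First-order upwinding smears lumen gradients axially; transport and heat
  content remain exact, but intra-lumen profiles are diffused.
* The controller observes the (noise-free) simulated midplane; it is a
  surrogate for feedback on measured thermometry, not a model of MRI noise,
  latency or resolution.
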