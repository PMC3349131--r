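# fusbioheat

Discrete-vessel bioheat simulation of focused-ultrasound (FUS) heating,
thermal dose and treatment delivery, for computational thermal-therapy
modelling: predicting how blood vessels of 0.3–3 mm diameter reshape the
temperature and necrosis-dose field around a FUS focus, and how different
sonication strategies (random, raster, spiral; fixed vs. feedback-capped
power) cope with that heterogeneity.

## The model

Tissue and vessel lumens are coupled through a shared temperature field
(two-domain bioheat model). Tissue obeys enhanced-conductivity conduction

    rho_t c_pt dT/dt = div(k_eff grad T) + P_FUS

and each straight cylindrical lumen adds axial convection with a parabolic
profile,

    rho_b c_pb dT/dt = div(k_b grad T) - rho_b c_pb w dT/dz + P_FUS,
    w(r) = 2 V_m (1 - r^2/R^2),

with flux continuity at the wall (no prescribed heat-transfer coefficient).
The deposited power is a separable Gaussian parameterized by its half-power
width/height, `P = P0 prod_u exp(-ln2 u^2/R_u^2)`. Thermal damage is
accumulated as CEM43 — cumulative equivalent minutes at 43 °C,
`TD = int R^(43-T) dt`, `R = 0.5` above 43 °C, `0.25` below — normalized by
the 240 eq-min necrosis threshold. Boundaries couple to the 37 °C core via
`h = k_eff/d`; vessel inlets are at 37 °C, outlets are pure outflow.

The solver is a finite-volume, backward-Euler locally-one-dimensional
scheme (implicit tridiagonal sweeps with upwind advection, compiled via
Rcpp), on full-3-D or axisymmetric grids. The methods vignette
(`vignettes/bioheat-methods.Rmd`) documents the discretization, its
validation against analytic kernels, and every default chosen where the
underlying description is silent.

## Worked example

A 60 s insonation of a secondary artery (R = 0.3 mm, L = 40 mm,
V_m = 8 cm/s) targeted on-axis, solved axisymmetrically:

```r
library(fusbioheat)
sc  <- preset_scenario("secondary_artery")
g   <- sim_grid(c(0.15e-3, 0.5e-3), c(0.03, 0.04), mode = "axisym")
f   <- rasterize(sc, g)
src <- fus_source(15, 4e-3, 30e-3, focus = c(0, 0.02), units = "W/cm3")
out <- simulate_heating(f, src, 60, solver_config(dt = 0.1))
out
#> <bh_state> t=60.00 s, T in [37.00, 61.24] C, peak dose 6.06e+04 eq-min
```

The focus reaches 61.2 °C — a 24.2 °C rise — and the peak accumulated dose
(6.1e4 eq-min, i.e. ~250× the 240 eq-min threshold) marks certain necrosis
at the focus: a vessel this small barely protects even its own lumen. Rerun
with `preset_scenario("large_artery")` and the peak rise drops to ~9 °C
with the lumen staying within ~0.6 °C of body temperature: fast-flowing
blood in a 3 mm vessel carries the deposited energy away.

Midplane dose statistics use the standard >0.3 normalized-dose mask:

```r
dose_stats(c(0.1, 0.4, 0.8))
#> <bh_dose_stats> peak 0.8; mask >0.3: n=2, mean 0.6, sd 0.2
```

Treatment-scale experiments (56 insonations, 20 s on / 5 s cool, 2 mm
focus grid, with or without per-event dose capping to 230–250 eq-min) live
in the numbered scripts under `analysis/`; each writes its tables to
`results/` and states its finding in the header comment.

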