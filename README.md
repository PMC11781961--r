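# valvefsi

Three-dimensional immersed-boundary/finite-element (IB/FE) simulation of a
bicuspid venous valve interacting with pulsatile blood flow.

Veins return blood against gravity, and their valves — pairs of semilunar
leaflets housed in a bulged sinus — open and close once per cardiac cycle.
Valve dysfunction (fibrosis, atrophy) and the near-stasis pockets behind
the leaflets are central to chronic venous insufficiency and deep-vein
thrombosis.  `valvefsi` is a research simulator for this system, aimed at
computational-hemodynamics users who want a self-contained, scriptable R
implementation: a parametric vein/sinus/leaflet mesh generator,
hyperelastic tissue mechanics, an incompressible staggered-grid flow
solver, delta-function fluid–structure coupling, disease scenarios, and
the post-processing used to characterise valve function.

## The model

Blood is an incompressible Newtonian fluid (density 1.08 g/cm³, dynamic
viscosity 0.036 Pa·s) on a fixed staggered Cartesian grid,

```
rho (u_t + u·grad u) = -grad p + mu lap u + f,     div u = 0,
```

driven through pressure boundary conditions on the vein mouths: a
sinusoidal forward difference `A sin(2 pi t / T)` (A = 0.5 mmHg, T = 1 s)
over the first half cycle, a small negative dip near end-cycle to assist
closure, and a hydrostatic offset of 4 mmHg at both ends.  The tissue is
an incompressible isotropic hyperelastic solid of three regions —
leaflets `Psi = c0 (I1-3) + c1 (I1-3)^2`, wall and sinus
`Psi = c2 {exp[c3 (I1-3)^2] - 1}` — plus a volumetric penalty
`beta/4 log^2 I3`, discretised with linear tetrahedra.  The first
Piola–Kirchhoff stress carries correction terms proportional to `F^{-T}`
so that the stress vanishes identically at the reference state.  Fluid
and structure exchange information through a regularised delta function
(Peskin 4-point kernel by default): weak-form elastic force densities are
spread to the grid, and mesh nodes move with the interpolated fluid
velocity.  Post-processing computes the geometric orifice area
(`GOA = pi/4 · D_major · D_minor` from the projected free edges),
transvalvular flow rate, cycle phase segmentation
(opening/equilibrium/closing/closed), stagnant-zone fraction
(speed < 1 cm/s), wall dilation `d/d0`, Tresca maximum shear stress
`(sigma1 - sigma3)/2` and maximum principal strain.

See `vignettes/valvefsi-methods.Rmd` for the full account, including how
the desk-scale presets define a scaled-down model of the reference
50 × 50 × 150 configuration.

## A worked example

```r
library(valvefsi)

# materials: the leaflet stress at 10% simple shear
leaflet <- material_params("polynomial", c0 = 4, c1 = 170.06)
F <- diag(3); F[1, 2] <- 0.1
pk1_stress(leaflet, F)[1, 2]
#> [1] 1.48024            # kPa; = (2 c0 + 4 c1 gamma^2) gamma

# geometry: the reference mesh
mesh <- build_structural_mesh(geometry_params(), resolution = 0.06)
mesh_quality_report(mesh)$n_elements
#> [1] 14688

# a desk-scale coupled run (two cardiac cycles, ~10 min on one core)
cfg <- preset_config("coarse16")
run <- run_simulation(cfg)
summary(run$metrics$GOA)
seg <- segment_phases(run$metrics$time[run$metrics$time > 1],
                      run$metrics$GOA[run$metrics$time > 1],
                      closed_area = 2 * pi/4 * 0.691 * cfg$geometry$g)
seg
#>         phase start   end fraction   (opening / equilibrium / closing / closed)
```

The GOA trace rises as the forward pressure difference opens the leaflets,
plateaus while the valve is fully open, falls as the difference decays,
and stays near the residual gap area through the reverse-pressure phase —
the four phases of the venous valve cycle.  `run$metrics` also carries the
transvalvular flow rate (cm³/s, distal→proximal positive), wall dilation,
stagnant-zone fraction and leaflet stress/strain maxima at each sample.

A command-line interface wraps the same functionality:

```sh
inst/cli/valvefsi mesh --preset coarse16 --output out/
inst/cli/valvefsi simulate --preset coarse16 --scenario fibrotic --output out/
inst/cli/valvefsi postprocess --metrics out/final_metrics.csv
inst/cli/valvefsi validate --quick
```

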