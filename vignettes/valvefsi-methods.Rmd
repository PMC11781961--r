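---
title: "Methods: an immersed-boundary/finite-element model of the venous valve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an immersed-boundary/finite-element model of the venous valve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`valvefsi` simulates a short segment of a lower-extremity vein containing a
bicuspid venous valve, fully coupled to the blood that flows through it.
The method is the immersed-boundary/finite-element (IB/FE) approach: blood
is an incompressible Newtonian fluid on a fixed staggered Cartesian grid,

$$\rho\,(\partial_t u + u\cdot\nabla u) = -\nabla p + \mu \nabla^2 u + f,
  \qquad \nabla\cdot u = 0,$$

while the vein wall, the valve sinus and the two leaflets are an elastic
solid discretised with linear tetrahedra in a Lagrangian reference frame.
The two talk to each other through a regularised Dirac delta
$\delta_h$: elastic force densities computed on the mesh are *spread* onto
the grid,

$$f(x) = \int_U F(X)\,\delta_h\!\big(x - \chi(X)\big)\,dX,$$

and mesh nodes move with the locally *interpolated* fluid velocity,

$$\dot\chi(X) = \int_\Omega u(x)\,\delta_h\!\big(x - \chi(X)\big)\,dx .$$

The Lagrangian force density is defined weakly: for every finite-element
test function $V$,

$$\int_U F\cdot V \, dX = -\int_U \mathbb{P} : \nabla_X V \, dX,$$

with $\mathbb{P}$ the first Piola–Kirchhoff stress.  With one-point
quadrature on linear tetrahedra and a lumped reference-volume mass matrix
this gives a nodal force density that is spread with the nodal reference
volumes as quadrature weights, making spreading and interpolation exact
discrete adjoints (the power identity that keeps the coupling
energy-consistent; it is asserted in the test suite to 1e-12).

### Tissue mechanics

Both tissue models are isotropic and incompressible, with a logarithmic
volumetric penalty.  Leaflets use the polynomial form
$\Psi = c_0(I_1-3) + c_1(I_1-3)^2$ with $c_0 = 4$ kPa, $c_1 = 170.06$;
wall and sinus use the exponential form
$\Psi = c_2\{\exp[c_3(I_1-3)^2]-1\}$ with $c_2 = 2$ kPa, $c_3 = 187.5$
(wall) and $c_2 = 0.5$ kPa, $c_3 = 46.875$ (sinus); all regions share the
penalty $\frac{\beta}{4}\log^2 I_3$ with $\beta = 500$ kPa.  The stress
includes correction terms proportional to $F^{-T}$ chosen so that
$\mathbb{P}(I) = 0$ exactly; pushed forward they act as a reference
pressure and reduce spurious volume loss across the interface.  Note a
structural property of the exponential form that matters throughout this
package: because its energy is quadratic in $(I_1-3)$, it has *zero*
small-strain shear modulus and stiffens violently once strains reach a few
per cent.  The (scalar) coefficient table is configurable; the package
binds coefficients to regions following the parameter table rather than
the equation subscripts (the two disagree in the source material for this
model class), and treats $c_1$, $c_3$ as dimensionless.

### Geometry

The reference geometry is a parametric idealisation of a bovine saphenous
vein segment: lumen diameter $d = 0.691$ cm, wall thickness 0.020 cm,
valve depth $l_v = 0.5$ cm, leaflet thickness 0.020 cm, sinus depth 1 cm,
sinus thickness 0.015 cm, vein length 3.2 cm truncated to the 3 cm fluid
box (1 cm x 1 cm x 3 cm).  The sinus bulge amplitude is not dimensioned in
the source; we use a $\sin^2$ radial bump with peak ratio 1.3 (a 1.4 bulge
would reach the lateral box faces).  Each leaflet midsurface is ruled
between a half-elliptic attachment curve of depth $l_v$ on the sinus wall
and a parabolic free edge in the valve plane whose midpoint stands half
the initialisation gap $g = 0.01$ cm off the symmetry plane, with a
parabolic belly sag (amplitude $0.2\,l_v$, shaped like $\sqrt{\sin\pi s}$
so the surface is not flat near the commissures).  The mesher generates a
structured annular wall grid (rotational generation), snaps one grid row
per angular column onto the attachment curve, mirrors the second leaflet,
and subdivides all cells with a globally consistent Freudenthal rule, so
wall, sinus and leaflets share nodes along their junction curves.
Columns whose attachment-to-free-edge chord is below the mesh resolution
(or below 2.5 leaflet thicknesses) are intrinsically flat slivers and are
left unmeshed; the free-edge curve still terminates on the commissure
wall nodes.  Because the free edge is a parabola that ends *on* the wall,
the distance between the two free edges equals $g$ at mid-edge and
decreases towards the commissures; the gap invariant is therefore
asserted at the free-edge midpoints.

### Fluid solver and boundary conditions

Staggered (MAC) finite differences; centred second-order convection with
a first-order upwind option used by the coarse presets (their cell
Reynolds number sits near the centred scheme's oscillation limit);
explicit midpoint (RK2) time staging; Chorin-style projection with the
pressure Poisson operator closed by Dirichlet ghost cells on all six
faces.  The factorisation of the Poisson operator is computed once per
grid (sparse Cholesky) and reused every step; periodic test grids use an
FFT solve.  Driving follows the one-second valve cycle: the
inlet/outlet difference is $A\sin 2\pi t$ with $A = 0.5$ mmHg over the
first half cycle, zero until $0.9$ s, and a small dip of $-0.05$ mmHg
(5 ms cosine ramps; the source states only "a small negative difference")
over the last tenth to assist closure.  Both ends carry a hydrostatic
offset $P_0 = 4$ mmHg.  Two discretisation choices here deserve note:

* the end-face pressures act over the vein mouth only (tapered to the
  zero exterior pressure across ~1.5 cells); applying them across the
  whole face drives a spurious exterior jet along the outside of the
  vein;
* $P_0$ is ramped in smoothly over `P0_ramp` (default 0.05 s; the coarse
  presets use 0.3 s) — an instantaneous 4 mmHg application is a pressure
  shock that no explicit scheme at these resolutions survives, and the
  physical statement being modelled is a quasi-statically applied
  hydrostatic head.

The time step must satisfy the advective CFL bound and the explicit
viscous bound $h^2\rho/6\mu$; `step_fsi()` enforces this with a
diagnostic.  The reference configuration uses $\Delta t = 10^{-5}$ s.

### Scenarios

`scenario_params()` implements the disease models: fibrotic leaflets
multiply all stress-like leaflet coefficients by 10, atrophic leaflets
divide them by 10, and venous hypertension raises the hydrostatic offset
above 30 mmHg while keeping the driving difference unchanged.  The
desk-scale scenario comparison (peak transvalvular flow of
atrophic > normal > fibrotic valves) is run under the valve-cycle drive
alone (no hydrostatic offset): the offset contributes no transvalvular
drive, and omitting it gives a controlled like-for-like comparison that
the stiffened fibrotic leaflet tolerates at coarse resolution.

## Desk-scale presets: the scaled-down model

Full-resolution runs (50 x 50 x 150 cells, $3\times10^5$ steps) are
workstation jobs.  The package therefore ships two desk presets,
`coarse16` (16 x 16 x 48, dt = 5e-5 s, 2 cycles) and `coarse32`
(32 x 32 x 96, dt = 2.5e-5 s), which are *models of the model*: at a
grid spacing of 0.0625 cm the 0.02 cm tissue sheets simply do not exist
for the fluid, and a scaled-down definition is required.  The presets:

* thicken wall and sinus to the local grid spacing (a sub-grid sheet has
  no resolvable bending behaviour and its internal modes receive no
  fluid damping);
* thicken the leaflets to 0.05 cm and rescale their stress-like
  coefficients by the thickness ratio, preserving the membrane stiffness
  (modulus x thickness) of the sheet while raising its bending stiffness
  — the standard thickness-compensation treatment for immersed shells;
* reduce the volumetric penalty to $\beta = 100$ kPa and add
  Kelvin–Voigt tissue damping ($\eta \dot F$, `damping_eta`), both of
  which trade incompressibility sharpness for an explicit stability
  margin;
* cap the exponential stiffening argument $c_3(I_1-3)^2$ at `exp_cap`
  (default 2 in the presets): the response is exact for wall strains
  below $(I_1-3) \approx 0.10$ — two orders of magnitude above the
  physiological static wall strain under these loads — and merely stops
  the *tangent stiffness* of spurious coarse-grid strain excursions from
  outrunning any explicit time step;
* use upwind convection and tether the wall within 2.5 cells of the box
  ends (the end rings plus the kernel-clamping layer, where a partially
  clamped delta kernel otherwise produces secular drift).

What the presets preserve: the geometry and pressure protocol, the
relative stiffness of leaflet/wall/sinus, the four-phase valve kinematics
and their pressure timing, flow directionality and scenario ordering.
What they do not: absolute flow magnitudes (the open orifice spans only a
few grid cells and the delta-function walls leak), wall shear magnitudes,
and grid-converged stresses.  Tests against the desk presets are
therefore qualitative/ordinal; quantitative reproduction belongs to the
`reference` preset run offline.

## Numerical choices and degenerate inputs

* Projection tolerance: direct sparse solves leave divergence at
  round-off; `project()` fails loudly if the residual exceeds
  `1e-8 * max|u| / h`.
* Phase segmentation locates the rising and falling flanks of a GOA
  trace between a closed threshold and 90% of the cycle maximum and
  extrapolates the flanks linearly to the closed and plateau levels:
  on a trapezoid trace this returns the corner times exactly and is
  insensitive to the two thresholds.
* The geometric orifice area uses the full axes,
  $GOA = \frac{\pi}{4} D_{major} D_{minor}$, with $D_{major}$ the
  commissure-to-commissure extent and $D_{minor}$ the maximum transverse
  separation of the projected free edges; contact within a tolerance
  yields zero.
* Tresca's maximum shear stress is evaluated on the Cauchy stress (the
  source does not specify the stress measure); the maximum principal
  strain is Green–Lagrange.
* Degenerate inputs fail loudly: inverted elements abort assembly with
  element ids, the mesher refuses resolutions that cannot resolve the
  wall thickness, and kernel supports that overlap the domain boundary
  are clamped with a warning.
* Simulations are deterministic by default; a seed only matters for the
  optional robustness jitter of initial node positions.

## Problem sizes used by the test-suite and acceptance runs

Unit and property tests use small periodic grids (8–32 cells per axis)
and meshes at 0.03–0.06 cm resolution.  The rigid-tube Poiseuille
validation runs at 32 x 32 x 96 with a tethered cylinder of radius
0.3455 cm.  The coupled smoke runs use the `coarse16` preset; paired
scenario runs integrate the opening half-cycle.  These sizes are chosen
so the whole suite completes in minutes on a single core while still
exercising every coupled pathway; they are not convergence claims.

## Known limitations

* No fibre reinforcement, viscoelasticity (beyond the numerical
  Kelvin–Voigt term) or active contraction; no leaflet contact model —
  closure is resisted hydrodynamically and by the reverse-pressure
  phase.
* No adaptive refinement or parallelism; the structured mesher is
  specific to the vein/sinus/bicuspid topology.
* Desk presets under-resolve the leaflet gap (0.01 cm vs 0.0625 cm
  cells), so closed-valve leakage is resolution-limited.
* The hypertension scenario (offset above 30 mmHg) produces tissue
  strains that only the reference-resolution configuration represents
  faithfully; at desk scale it is exercised for configuration logic
  only.
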