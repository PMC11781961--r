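Package: valvefsi
Title: Immersed-Boundary Finite-Element Simulation of Venous Valve
    Fluid-Structure Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-dimensional immersed-boundary/finite-element (IB/FE)
    simulator of a bicuspid venous valve immersed in pulsatile blood flow.
    Generates a parametric vein, sinus and leaflet mesh, models the tissue
    with incompressible hyperelastic strain energies (polynomial and
    exponential forms with a logarithmic volumetric penalty), solves the
    incompressible Navier-Stokes equations on a staggered Cartesian grid
    with a pressure-projection scheme, and couples structure and fluid
    through regularised delta-function force spreading and velocity
    interpolation.  Post-processing computes geometric orifice area,
    transvalvular flow rate, valve-cycle phase segmentation, stagnant-zone
    fractions, wall dilation, Tresca maximum shear stress and maximum
    principal strain.  Includes normal, fibrotic, atrophic and venous
    hypertension scenarios and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
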