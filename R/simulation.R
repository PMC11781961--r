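MMHG <- 1333.22  # dyn/cm^2 per mmHg

#' Driving pressure profile over the valve cycle
#'
#' Inlet/outlet pressure protocol of one cardiac cycle of length `T`:
#' the pressure difference follows `A sin(2 pi t / T)` over the first half
#' cycle, is zero until `0.9 T`, and holds a small negative dip `-eps`
#' over the final tenth of the cycle (with short cosine ramps) to assist
#' valve closure.  Both ends carry the hydrostatic offset `P0`; the outlet
#' stays at `P0` and the inlet at `P0 + dp`.
#'
#' @param amplitude peak forward pressure difference A (mmHg).
#' @param P0 hydrostatic offset applied to both ends (mmHg).
#' @param period cycle length T (s).
#' @param eps closing dip magnitude (mmHg, >= 0).
#' @param ramp ramp time into/out of the dip (s).
#' @param P0_ramp start-up time (s) over which the hydrostatic offset is
#'   raised smoothly from 0 to `P0` (quasi-static application of the
#'   initial hydrostatic pressure; once only, not per cycle).
#' @return A `pressure_profile` object.
#' @export
pressure_profile <- function(amplitude = 0.5, P0 = 4, period = 1,
                             eps = 0.05, ramp = 0.005, P0_ramp = 0.05) {
  stopifnot(amplitude >= 0, period > 0, eps >= 0, ramp >= 0,
            ramp < period / 20, P0_ramp >= 0)
  structure(list(A = amplitude, P0 = P0, T = period, eps = eps,
                 ramp = ramp, P0_ramp = P0_ramp), class = "pressure_profile")
}

#' Inlet and outlet pressures at time t
#'
#' @param t time (s, scalar or vector, >= 0).
#' @param spec a [pressure_profile].
#' @return Matrix with columns `p_in`, `p_out` (mmHg).
#' @export
inlet_outlet_pressures <- function(t, spec = pressure_profile()) {
  if (any(t < 0)) stop("time must be non-negative")
  tau <- t %% spec$T
  Tc <- spec$T; r <- spec$ramp
  dp <- ifelse(tau <= Tc / 2, spec$A * sin(2 * pi * tau / Tc), 0)
  if (spec$eps > 0) {
    t0 <- 0.9 * Tc
    in_ramp1 <- tau >= t0 & tau < t0 + r
    in_hold  <- tau >= t0 + r & tau < Tc - r
    in_ramp2 <- tau >= Tc - r
    dp[in_ramp1] <- -spec$eps * (1 - cos(pi * (tau[in_ramp1] - t0) / r)) / 2
    dp[in_hold]  <- -spec$eps
    dp[in_ramp2] <- -spec$eps * (1 - cos(pi * (Tc - tau[in_ramp2]) / r)) / 2
  }
  P0 <- rep(spec$P0, length(dp))
  if (spec$P0_ramp > 0) {
    s <- pmin(t / spec$P0_ramp, 1)
    P0 <- P0 * s^2 * (3 - 2 * s)       # smoothstep start-up
  }
  cbind(p_in = P0 + dp, p_out = P0)
}

#' Disease-scenario material transforms
#'
#' Fibrotic valves are modelled by stiffening the leaflets tenfold,
#' atrophic valves by softening them tenfold: all stress-like leaflet
#' coefficients are multiplied or divided by 10.  The hypertension
#' scenario leaves the tissue unchanged (its boundary-pressure offset is
#' raised instead), as does `normal`.
#'
#' @param base named list of per-region [material_params].
#' @param scenario one of `"normal"`, `"fibrotic"`, `"atrophic"`,
#'   `"hypertension"`.
#' @return Modified list of materials.
#' @export
scenario_params <- function(base,
                            scenario = c("normal", "fibrotic", "atrophic",
                                         "hypertension")) {
  scenario <- match.arg(scenario)
  fac <- switch(scenario, fibrotic = 10, atrophic = 0.1, 1)
  if (fac == 1) return(base)
  lf <- base$leaflet
  if (lf$model_form == "polynomial") {
    lf$c0 <- lf$c0 * fac; lf$c1 <- lf$c1 * fac
  } else {
    lf$c2 <- lf$c2 * fac
  }
  base$leaflet <- lf
  base
}

#' Simulation configuration
#'
#' Bundles geometry, materials, grid, pressure protocol and numerical
#' settings of one fluid--structure simulation.  The defaults reproduce
#' the reference configuration: 50 x 50 x 150 fluid cells over a
#' 1 x 1 x 3 cm box, dt = 1e-5 s, three 1 s cycles, with the vein
#' truncated to the box length.  Use [preset_config] for ready-made
#' desk-scale presets.
#'
#' @param geometry a [geometry_params]; its length is truncated to the
#'   fluid box length (with a message) if it exceeds it.
#' @param materials per-region materials, see [default_materials].
#' @param grid_n fluid cell counts.
#' @param box fluid box extents (cm).
#' @param profile a [pressure_profile].
#' @param dt time step (s).
#' @param cycles number of cardiac cycles.
#' @param rho,mu blood density (g/cm^3) and viscosity (g/(cm s)).
#' @param struct_resolution structural target edge length (cm).
#' @param tether_kappa end-fixation penalty stiffness (dyn/cm^3 per cm).
#' @param fix_margin axial extent (cm) of the tethered end bands; `NULL`
#'   tethers wall nodes within 2.5 fluid cells of the box ends (the end
#'   rings plus the rows inside the kernel-clamping layer).
#' @param kernel delta-function family, see [ib_kernel].
#' @param scenario disease scenario; `"fibrotic"`/`"atrophic"` rescale the
#'   leaflet stiffness, `"hypertension"` raises the hydrostatic offset to
#'   `hypertension_P0`.
#' @param hypertension_P0 offset (mmHg) used by the hypertension scenario.
#' @param output_every sample metrics every this many steps.
#' @param rk_stages 2 for the midpoint scheme (default), 1 for forward
#'   Euler.
#' @param damping_eta Kelvin--Voigt tissue damping (kPa s); see
#'   [assemble_internal_forces].
#' @param upwind use first-order upwind convection (coarse grids); see
#'   [advect_diffuse].
#' @param smooth_eta implicit Lagrangian velocity-smoothing viscosity
#'   (g/(cm s)); 0 disables.  See [velocity_smoother].
#' @param exp_cap tangent-stiffness limiter for the exponential tissues;
#'   see [assemble_internal_forces].
#' @param bedding_kappa weak elastic bedding (dyn/cm^3 per cm) tying wall
#'   and sinus nodes to their reference positions.  The exponential
#'   tissues have no small-strain shear stiffness, so at coarse
#'   resolutions slow leak-driven stirring can skew shell elements
#'   secularly; a bedding 1-2 orders of magnitude below the pressure
#'   loading scale removes the drift without noticeably stiffening the
#'   static response.  0 disables (reference preset).
#' @param seed optional seed for the (optional) initial node jitter.
#' @param jitter amplitude (cm) of random node jitter, default 0 (off).
#' @return A `sim_config` object.
#' @export
sim_config <- function(geometry = geometry_params(),
                       materials = default_materials(),
                       grid_n = c(50L, 50L, 150L), box = c(1, 1, 3),
                       profile = pressure_profile(),
                       dt = 1e-5, cycles = 3L,
                       rho = 1.08, mu = 0.36,
                       struct_resolution = 0.02,
                       tether_kappa = 5e6,
                       fix_margin = NULL,
                       kernel = "ib4",
                       scenario = "normal",
                       hypertension_P0 = 32,
                       output_every = 100L,
                       rk_stages = 2L,
                       damping_eta = 0, upwind = FALSE,
                       smooth_eta = 0, exp_cap = Inf,
                       bedding_kappa = 0,
                       seed = NULL, jitter = 0) {
  stopifnot(dt > 0, cycles >= 1, rk_stages %in% c(1L, 2L))
  if (geometry$l > box[3]) {
    message("vein length ", geometry$l, " cm truncated to the fluid box ",
            "length ", box[3], " cm")
    sc <- box[3] / geometry$l
    geometry <- geometry_params(
      l = box[3], d = geometry$d, tw = geometry$tw, lv = geometry$lv,
      tv = geometry$tv, ls = geometry$ls, ts = geometry$ts,
      sinus_bulge_ratio = geometry$sinus_bulge_ratio, g = geometry$g,
      valve_z = geometry$valve_z * sc, sinus_offset = geometry$sinus_offset,
      sag = geometry$sag)
  }
  scenario <- match.arg(scenario,
                        c("normal", "fibrotic", "atrophic", "hypertension"))
  materials_base <- materials
  materials <- scenario_params(materials, scenario)
  if (scenario == "hypertension")
    profile <- pressure_profile(profile$A, hypertension_P0, profile$T,
                                profile$eps, profile$ramp, profile$P0_ramp)
  cfg <- list(geometry = geometry, materials = materials,
              materials_base = materials_base,
              grid_n = as.integer(grid_n), box = box, profile = profile,
              dt = dt, cycles = as.integer(cycles), rho = rho, mu = mu,
              struct_resolution = struct_resolution,
              tether_kappa = tether_kappa, fix_margin = fix_margin,
              kernel = kernel,
              scenario = scenario, output_every = as.integer(output_every),
              rk_stages = as.integer(rk_stages),
              damping_eta = damping_eta, upwind = isTRUE(upwind),
              smooth_eta = smooth_eta, exp_cap = exp_cap,
              bedding_kappa = bedding_kappa,
              seed = seed, jitter = jitter)
  class(cfg) <- "sim_config"
  cfg
}

#' Desk-scale and reference presets
#'
#' * `"reference"`: the full-resolution configuration (50 x 50 x 150
#'   grid, dt = 1e-5 s, 3 cycles, beta = 500 kPa, exact materials).
#'   Intended for long runs on a workstation, not interactive use.
#' * `"coarse32"`: 32 x 32 x 96 grid, softened volumetric penalty and
#'   enlarged dt; for validation studies.
#' * `"coarse16"`: 16 x 16 x 48 smoke-test preset, 2 cycles.
#'
#' The coarse presets scale the volumetric penalty and tether stiffness
#' down with resolution so the explicit stability limit allows a larger
#' time step; incompressibility is then enforced more loosely, which is
#' acceptable at these resolutions (see the methods vignette).
#'
#' @param name preset name.
#' @param scenario passed to [sim_config].
#' @param cycles number of cycles (defaults per preset).
#' @param ... further overrides forwarded to [sim_config].
#' @return A `sim_config`.
#' @export
preset_config <- function(name = c("coarse16", "coarse32", "reference"),
                          scenario = "normal", cycles = NULL, ...) {
  name <- match.arg(name)
  args <- switch(name,
    reference = list(grid_n = c(50L, 50L, 150L), dt = 1e-5,
                 cycles = if (is.null(cycles)) 3L else cycles,
                 struct_resolution = 0.02, tether_kappa = 5e6,
                 materials = default_materials(beta = 500),
                 output_every = 1000L),
    coarse32 = list(grid_n = c(32L, 32L, 96L), dt = 2e-5,
                    cycles = if (is.null(cycles)) 2L else cycles,
                    struct_resolution = 0.045, tether_kappa = 1e7,
                    materials = thickness_compensated(
                      default_materials(beta = 200), 0.02 / 0.032),
                    geometry = geometry_params(tw = 0.032, ts = 0.032,
                                               tv = 0.032, g = 0.025),
                    profile = pressure_profile(P0_ramp = 0.3),
                    damping_eta = 0.01, upwind = TRUE, exp_cap = 2,
                    bedding_kappa = 1e5,
                    output_every = 500L),
    coarse16 = list(grid_n = c(16L, 16L, 48L), dt = 4e-5,
                    cycles = if (is.null(cycles)) 2L else cycles,
                    struct_resolution = 0.06, tether_kappa = 1e7,
                    materials = thickness_compensated(
                      default_materials(beta = 200), 0.02 / 0.05),
                    geometry = geometry_params(tw = 0.0625, ts = 0.0625,
                                               tv = 0.05, g = 0.05),
                    profile = pressure_profile(P0_ramp = 0.3),
                    damping_eta = 0.02, upwind = TRUE, exp_cap = 2,
                    bedding_kappa = 1e5,
                    output_every = 250L))
  do.call(sim_config, c(args, list(scenario = scenario), list(...)))
}

#' Membrane-stiffness compensation for numerically thickened leaflets
#'
#' When a desk-scale preset inflates the leaflet thickness to what the
#' fluid grid can resolve, the leaflet stress-like coefficients are scaled
#' by the thickness ratio `t_true / t_numerical` so the membrane stiffness
#' (modulus x thickness) of the sheet is preserved; the bending stiffness
#' increases, which stabilises the one-element-thick sheet.
#'
#' @param materials per-region material list.
#' @param factor thickness ratio (true / numerical), in (0, 1].
#' @return Modified material list (leaflet entry rescaled).
#' @export
thickness_compensated <- function(materials, factor) {
  lf <- materials$leaflet
  if (lf$model_form == "polynomial") {
    lf$c0 <- lf$c0 * factor; lf$c1 <- lf$c1 * factor
  } else {
    lf$c2 <- lf$c2 * factor
  }
  materials$leaflet <- lf
  materials
}

## assemble all Lagrangian force densities (elastic + tethers), in CGS
total_structure_forces <- function(mesh, x, cfg, xdot = NULL) {
  el <- assemble_internal_forces(mesh, x, cfg$materials,
                                 xdot = xdot, eta = cfg$damping_eta,
                                 exp_cap = cfg$exp_cap)
  fd <- el$force_density + tether_forces(mesh, x, cfg$tether_kappa)
  if (cfg$bedding_kappa > 0) {
    wn <- mesh$cache$wall_nodes
    if (is.null(wn)) {
      wn <- unique(as.vector(mesh$elements[mesh$region != "leaflet", ]))
      mesh$cache$wall_nodes <- wn
    }
    fd[wn, ] <- fd[wn, ] + cfg$bedding_kappa *
      (mesh$nodes[wn, , drop = FALSE] - x[wn, , drop = FALSE])
  }
  list(force_density = fd, F = el$F, energy = el$energy)
}

#' Initialise the coupled simulation state
#'
#' @param cfg a [sim_config].
#' @return A `fsi_state`: structural mesh, node positions, fluid state,
#'   time and step counter.
#' @export
init_simulation <- function(cfg) {
  mesh <- build_structural_mesh(cfg$geometry, cfg$struct_resolution)
  grid <- fluid_grid(cfg$grid_n, cfg$box)
  fluid <- fluid_state(grid, rho = cfg$rho, mu = cfg$mu)
  x <- mesh$nodes
  ## centre the vein on the box axis (mesh axis is x = y = 0)
  x[, 1] <- x[, 1] + cfg$box[1] / 2
  x[, 2] <- x[, 2] + cfg$box[2] / 2
  mesh$nodes <- x                      # reference follows the embedding
  mesh$cache <- new.env(parent = emptyenv())
  ## tether the full end bands: the end rings plus the wall rows inside
  ## the kernel-clamping layer next to the box faces
  margin <- if (is.null(cfg$fix_margin)) 2.5 * grid$h else cfg$fix_margin
  band <- which(x[, 3] < margin | x[, 3] > cfg$box[3] - margin)
  mesh$fixed <- sort(union(mesh$fixed, band))
  if (!is.null(cfg$seed) && cfg$jitter > 0) {
    set.seed(cfg$seed)
    interior <- setdiff(seq_len(nrow(x)), mesh$fixed)
    x[interior, ] <- x[interior, ] +
      matrix(stats::rnorm(3 * length(interior), sd = cfg$jitter),
             ncol = 3)
    mesh$cache <- new.env(parent = emptyenv())
  }
  ## end-face lumen mask: driving pressures act over the vein mouth only,
  ## tapering to the zero exterior pressure over ~1.5 cells at the wall so
  ## the wall edge does not sit inside a one-cell pressure jump
  xc <- (seq_len(cfg$grid_n[1]) - 0.5) * grid$h - cfg$box[1] / 2
  yc <- (seq_len(cfg$grid_n[2]) - 0.5) * grid$h - cfg$box[2] / 2
  rr <- sqrt(outer(xc, yc, function(a, b) a^2 + b^2))
  end_mask <- pmin(pmax((cfg$geometry$d / 2 - rr) / (1.5 * grid$h), 0), 1)
  st <- list(mesh = mesh, x = x, fluid = fluid, t = 0, step = 0L,
             kernel = ib_kernel(cfg$kernel), end_mask = end_mask)
  class(st) <- "fsi_state"
  st
}

#' Advance the coupled FSI system by one time step
#'
#' Midpoint (RK2) staging of the full coupling: interpolate velocities,
#' advance structure to the half step, evaluate and spread elastic and
#' tether forces there, advance the fluid with pressure boundary
#' conditions, project, and move the structure with the midpoint velocity.
#'
#' @param st an `fsi_state`.
#' @param cfg the [sim_config].
#' @return Advanced state.
#' @export
step_fsi <- function(st, cfg) {
  dt <- cfg$dt
  mesh <- st$mesh; fl <- st$fluid; kern <- st$kernel
  fe <- fe_precompute(mesh)
  pb <- inlet_outlet_pressures(st$t + dt / 2, cfg$profile) * MMHG
  pb_end <- inlet_outlet_pressures(st$t + dt, cfg$profile) * MMHG

  dt_ok <- stable_dt(fl, cfl = 1)
  if (dt > dt_ok * (1 + 1e-9))
    stop("step ", st$step, ": dt = ", dt, " s violates the stability ",
         "bound ", signif(dt_ok, 4), " s (max speed ",
         signif(max_speed(fl), 4), " cm/s)")

  warn <- st$step == 0L
  if (cfg$rk_stages == 1L) {
    fr <- total_structure_forces(mesh, st$x, cfg)
    fl <- ib_spread(st$x, fr$force_density, fe$nodal_vol, fl, kern,
                    warn = warn)
    fl <- apply_pressure_bcs(fl, pb_end[1], pb_end[2], st$end_mask)
    fl <- advect_diffuse(fl, dt, check_cfl = FALSE, upwind = cfg$upwind)
    fl <- project(fl, dt, check = st$step %% 100L == 0L)
    U <- ib_interpolate(fl, st$x, kern, warn = warn)
    if (cfg$smooth_eta > 0)
      U <- velocity_smoother(mesh, cfg$smooth_eta, dt)(U)
    st$x <- st$x + dt * U
  } else {
    ## half step: move structure to the midpoint, evaluate forces there
    U0 <- ib_interpolate(fl, st$x, kern, warn = warn)
    xh <- st$x + dt / 2 * U0
    fr <- total_structure_forces(mesh, xh, cfg, xdot = U0)
    flh <- ib_spread(xh, fr$force_density, fe$nodal_vol, fl, kern,
                     warn = warn)
    flh <- apply_pressure_bcs(flh, pb[1], pb[2], st$end_mask)
    flh <- advect_diffuse(flh, dt / 2, check_cfl = FALSE,
                          upwind = cfg$upwind)
    flh <- project(flh, dt / 2, check = FALSE)
    ## full step with the midpoint right-hand side (the body force of the
    ## midpoint configuration is still attached to flh)
    adv <- advect_diffuse(flh, dt, check_cfl = FALSE, upwind = cfg$upwind)
    fl$u <- st$fluid$u + (adv$u - flh$u)
    fl$v <- st$fluid$v + (adv$v - flh$v)
    fl$w <- st$fluid$w + (adv$w - flh$w)
    fl <- apply_pressure_bcs(fl, pb_end[1], pb_end[2], st$end_mask)
    fl <- project(fl, dt, check = st$step %% 100L == 0L)
    Uh <- ib_interpolate(flh, xh, kern, warn = FALSE)
    if (cfg$smooth_eta > 0)
      Uh <- velocity_smoother(mesh, cfg$smooth_eta, dt)(Uh)
    st$x <- st$x + dt * Uh
  }
  fl$t <- st$t + dt
  st$fluid <- fl
  st$t <- st$t + dt
  st$step <- st$step + 1L
  st
}

#' Run a coupled simulation
#'
#' Advances the configured number of cardiac cycles, sampling metrics
#' every `cfg$output_every` steps, and logs the cycle-to-cycle relative
#' change of the peak transvalvular flow rate.
#'
#' @param cfg a [sim_config].
#' @param checkpoint_file optional path; the full state is saved there
#'   every cycle and the run can be resumed with `restart`.
#' @param restart optional `fsi_state` (or path to a checkpoint) to resume
#'   from.
#' @param progress print a per-cycle summary line.
#' @return List with `metrics` (data frame), `state` (final `fsi_state`),
#'   `mesh`, `config` and `cycle_peak_Q`.
#' @export
run_simulation <- function(cfg, checkpoint_file = NULL, restart = NULL,
                           progress = interactive()) {
  st <- if (is.null(restart)) init_simulation(cfg)
        else if (is.character(restart)) readRDS(restart)
        else restart
  steps_per_cycle <- round(cfg$profile$T / cfg$dt)
  n_steps <- cfg$cycles * steps_per_cycle
  rows <- list()
  peakQ <- numeric(0)
  zs <- sinus_window(st$mesh$params)
  while (st$step < n_steps) {
    st <- step_fsi(st, cfg)
    if (st$step %% cfg$output_every == 0L) {
      rows[[length(rows) + 1L]] <- sample_metrics(st, cfg)
    }
    if (st$step %% steps_per_cycle == 0L) {
      cyc <- st$step %/% steps_per_cycle
      m <- do.call(rbind, rows)
      qc <- m$Q[m$time > (cyc - 1) * cfg$profile$T]
      peakQ <- c(peakQ, max(qc))
      if (length(peakQ) > 1) {
        rel <- abs(diff(utils::tail(peakQ, 2))) / max(abs(peakQ), 1e-12)
        if (progress)
          message(sprintf("cycle %d: peak Q = %.4g cm^3/s (rel change %.2g)",
                          cyc, utils::tail(peakQ, 1), rel))
      } else if (progress) {
        message(sprintf("cycle %d: peak Q = %.4g cm^3/s", cyc,
                        utils::tail(peakQ, 1)))
      }
      if (!is.null(checkpoint_file)) saveRDS(st, checkpoint_file)
    }
  }
  metrics <- do.call(rbind, rows)
  list(metrics = metrics, state = st, mesh = st$mesh, config = cfg,
       cycle_peak_Q = peakQ)
}

sinus_window <- function(params) {
  zs0 <- params$valve_z - params$sinus_offset * params$ls
  c(zs0, zs0 + params$ls)
}

## one metrics row for the current state
sample_metrics <- function(st, cfg) {
  mesh <- st$mesh; x <- st$x
  prm <- mesh$params
  fe1 <- x[mesh$free_edges[[1]], , drop = FALSE]
  fe2 <- x[mesh$free_edges[[2]], , drop = FALSE]
  goa <- geometric_orifice_area(fe1, fe2, closed_tol = prm$g / 4)
  Q <- transvalvular_flow_rate(st$fluid, prm$valve_z,
                               lumen_mask(st$fluid$grid, prm,
                                          prm$valve_z, cfg$box))
  dil <- dilation_ratio(mesh, x,
                        measurement_z = sinus_window(prm)[1] / 2)
  stag <- stagnant_fraction(st$fluid, sinus_pocket_mask(st$fluid$grid, prm,
                                                        cfg$box))
  lm <- leaflet_max_measures(mesh, x, cfg$materials)
  vol <- sum(tet_volumes(x, mesh$elements))
  pb <- inlet_outlet_pressures(st$t, cfg$profile)
  data.frame(time = st$t, step = st$step, GOA = goa, Q = Q,
             p_in = pb[1], p_out = pb[2],
             dilation = dil, stagnant_fraction = stag,
             max_tresca = lm$max_tresca,
             max_principal_strain = lm$max_strain,
             structure_volume = vol,
             max_speed = max_speed(st$fluid))
}

## closed-form eigenvalue extremes of batched symmetric 3x3 matrices
## (rows: s11, s22, s33, s12, s13, s23); trigonometric method
sym3_eig_range <- function(S) {
  p1 <- S[, 4]^2 + S[, 5]^2 + S[, 6]^2
  q <- (S[, 1] + S[, 2] + S[, 3]) / 3
  p2 <- (S[, 1] - q)^2 + (S[, 2] - q)^2 + (S[, 3] - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  b11 <- S[, 1] - q; b22 <- S[, 2] - q; b33 <- S[, 3] - q
  detB <- b11 * (b22 * b33 - S[, 6]^2) -
          S[, 4] * (S[, 4] * b33 - S[, 6] * S[, 5]) +
          S[, 5] * (S[, 4] * S[, 6] - b22 * S[, 5])
  r <- ifelse(p > 0, detB / 2 / p^3, 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  emax <- q + 2 * p * cos(phi)
  emin <- q + 2 * p * cos(phi + 2 * pi / 3)
  cbind(emin, emax)
}

## maximum Tresca shear stress and principal strain over leaflet elements
leaflet_max_measures <- function(mesh, x, materials) {
  sel <- mesh$region == "leaflet"
  F <- fe_deformation_gradients(mesh, x)[sel, , drop = FALSE]
  P <- pk1_batch(materials$leaflet, F)
  J <- det3_batch(F)
  ok <- J > 0
  F <- F[ok, , drop = FALSE]; P <- P[ok, , drop = FALSE]; J <- J[ok]
  ## sigma = P F^T / J, symmetric for these isotropic laws
  ii <- function(i, j) i + 3L * (j - 1L)
  sig <- function(i, j)
    (P[, ii(i, 1)] * F[, ii(j, 1)] + P[, ii(i, 2)] * F[, ii(j, 2)] +
     P[, ii(i, 3)] * F[, ii(j, 3)]) / J
  Ssig <- cbind(sig(1, 1), sig(2, 2), sig(3, 3),
                sig(1, 2), sig(1, 3), sig(2, 3))
  er <- sym3_eig_range(Ssig)
  mt <- max((er[, 2] - er[, 1]) / 2, 0)
  ## Green-Lagrange strain E = (F^T F - I)/2
  ct <- function(i, j)
    (F[, ii(1, i)] * F[, ii(1, j)] + F[, ii(2, i)] * F[, ii(2, j)] +
     F[, ii(3, i)] * F[, ii(3, j)])
  SE <- cbind((ct(1, 1) - 1) / 2, (ct(2, 2) - 1) / 2, (ct(3, 3) - 1) / 2,
              ct(1, 2) / 2, ct(1, 3) / 2, ct(2, 3) / 2)
  ms <- max(sym3_eig_range(SE)[, 2], 0)
  list(max_tresca = mt, max_strain = ms)
}
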