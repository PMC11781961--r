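#' Staggered (MAC) fluid grid
#'
#' Uniform Cartesian grid for the incompressible Navier--Stokes solver.
#' Velocity components live on cell faces, pressure at cell centres.
#' The default matches the reference configuration: a 1 x 1 x 3 cm box
#' with 50 x 50 x 150 cells (h = 0.02 cm).
#'
#' @param n integer cell counts per axis (length 3, each >= 8).
#' @param L box extents in cm (length 3).
#' @param periodic logical; periodic closure on all axes (test mode used for
#'   spectral checks; physical runs use open traction boundaries).
#' @return A `fluid_grid` object.
#' @export
fluid_grid <- function(n = c(50L, 50L, 150L), L = c(1, 1, 3),
                       periodic = FALSE) {
  n <- as.integer(n)
  stopifnot(length(n) == 3L, length(L) == 3L, all(L > 0))
  if (any(n < 8L)) stop("at least 8 cells per axis are required")
  h <- L / n
  if (diff(range(h)) > 1e-12 * max(h))
    stop("grid spacing must be isotropic: got h = ",
         paste(signif(h, 6), collapse = ", "))
  g <- list(n = n, L = as.numeric(L), h = h[1], periodic = isTRUE(periodic),
            cache = new.env(parent = emptyenv()))
  class(g) <- "fluid_grid"
  g
}

#' @export
print.fluid_grid <- function(x, ...) {
  cat("<fluid_grid> ", paste(x$n, collapse = " x "),
      " cells, box ", paste(x$L, collapse = " x "),
      " cm, h = ", x$h, " cm", if (x$periodic) ", periodic" else "", "\n",
      sep = "")
  invisible(x)
}

stag_dims <- function(grid, comp) {
  n <- grid$n
  if (grid$periodic) return(n)
  switch(comp, u = n + c(1L, 0L, 0L), v = n + c(0L, 1L, 0L),
         w = n + c(0L, 0L, 1L))
}

#' Fluid state on a MAC grid
#'
#' Face-centred velocities (cm/s), cell-centred pressure (dyn/cm^2) and
#' face-centred body force (dyn/cm^3).  Defaults are venous blood at rest:
#' density 1.08 g/cm^3, dynamic viscosity 0.036 Pa s = 0.36 g/(cm s).
#'
#' @param grid a [fluid_grid].
#' @param rho fluid density (g/cm^3).
#' @param mu dynamic viscosity (g/(cm s)).
#' @return A `fluid_state` object at rest, time 0.
#' @export
fluid_state <- function(grid, rho = 1.08, mu = 0.36) {
  z <- function(comp) array(0, stag_dims(grid, comp))
  s <- list(grid = grid,
            u = z("u"), v = z("v"), w = z("w"),
            fx = z("u"), fy = z("v"), fz = z("w"),
            p = array(0, grid$n), t = 0,
            rho = rho, mu = mu,
            ## lateral boundary pressures (scalars) and end-face pressure
            ## fields (nx x ny), dyn/cm^2
            pbc = numeric(4),
            pz0 = matrix(0, grid$n[1], grid$n[2]),
            pz1 = matrix(0, grid$n[1], grid$n[2]))
  class(s) <- "fluid_state"
  s
}

#' Apply boundary pressures
#'
#' Sets the open-boundary normal-traction values: `p_in` on the z-min
#' (distal) face, `p_out` on the z-max (proximal) face, zero on the four
#' lateral faces and on the remainder of the end faces outside the vein
#' lumen when a `mask` is given.  Tangential velocity carries a
#' zero-gradient condition.  The values enter the pressure Poisson solve
#' and face-pressure gradients as Dirichlet ghost-cell conditions.
#'
#' @param state a [fluid_state].
#' @param p_in,p_out inlet/outlet pressures (dyn/cm^2).
#' @param mask optional nx x ny logical matrix marking the lumen area of
#'   the end faces; outside it the end-face pressure is zero.  `NULL`
#'   applies the pressures over the whole face.
#' @return The state with boundary values recorded.
#' @export
apply_pressure_bcs <- function(state, p_in, p_out, mask = NULL) {
  if (state$grid$periodic) stop("pressure BCs require a non-periodic grid")
  n <- state$grid$n
  if (is.null(mask)) mask <- matrix(TRUE, n[1], n[2])
  state$pz0 <- p_in * mask
  state$pz1 <- p_out * mask
  state
}

#' MAC divergence of the velocity field
#'
#' @param state a [fluid_state].
#' @return Cell-centred divergence array (1/s).
#' @export
divergence <- function(state) {
  g <- state$grid
  array(cpp_divergence(state$u, state$v, state$w, g$n[1], g$n[2], g$n[3],
                       g$h, g$periodic), g$n)
}

max_speed <- function(state) {
  max(abs(range(state$u)), abs(range(state$v)), abs(range(state$w)))
}

#' Explicit stability bound on the time step
#'
#' Combines the advective CFL limit and the explicit viscous bound
#' `h^2 rho / (6 mu)`.
#'
#' @param state a [fluid_state].
#' @param cfl advective safety factor.
#' @return Largest admissible dt (s).
#' @export
stable_dt <- function(state, cfl = 0.5) {
  h <- state$grid$h
  dt_visc <- h^2 * state$rho / (6 * state$mu)
  umax <- max_speed(state)
  if (umax > 0) min(dt_visc, cfl * h / umax) else dt_visc
}

#' Advection--diffusion substep
#'
#' One explicit update of the momentum equation without the pressure
#' gradient: `u* = u + dt (-(u.grad)u + (mu/rho) lap u + f/rho)`.
#' Centred second-order stencils; zero-normal-gradient velocity ghosts at
#' open boundaries, wrap-around in periodic test mode.
#'
#' @param state a [fluid_state] (body force taken from `state$fx/fy/fz`).
#' @param dt time step (s); must satisfy the advective CFL condition and
#'   the explicit viscous bound.
#' @param check_cfl logical; set `FALSE` to skip the stability check
#'   (used inside multi-stage steps that have already verified it).
#' @param upwind logical; use first-order upwind differencing for the
#'   convective term instead of the centred second-order form (adds
#'   numerical dissipation; useful at coarse resolutions where the cell
#'   Reynolds number approaches the centred scheme's oscillation limit).
#' @return State with the intermediate velocity.
#' @export
advect_diffuse <- function(state, dt, check_cfl = TRUE, upwind = FALSE) {
  g <- state$grid
  if (check_cfl) {
    dt_ok <- stable_dt(state, cfl = 1)
    if (dt > dt_ok * (1 + 1e-12))
      stop("time step ", dt, " s violates the explicit stability bound; ",
           "use dt <= ", signif(dt_ok, 4), " s")
  }
  res <- cpp_advect_diffuse(state$u, state$v, state$w,
                            state$fx, state$fy, state$fz,
                            g$n[1], g$n[2], g$n[3], g$h, dt,
                            state$rho, state$mu, g$periodic, upwind)
  state$u <- array(res$u, stag_dims(g, "u"))
  state$v <- array(res$v, stag_dims(g, "v"))
  state$w <- array(res$w, stag_dims(g, "w"))
  state
}

## Build and cache the SPD pressure Poisson operator (negative Laplacian
## with Dirichlet ghost-cell closure on all six faces), and its Cholesky
## factorisation.  Cells indexed column-major i + nx (j + ny k).
poisson_factor <- function(grid) {
  if (!is.null(grid$cache$chol)) return(grid$cache$chol)
  n <- grid$n; nx <- n[1]; ny <- n[2]; nz <- n[3]
  N <- nx * ny * nz
  idx <- function(i, j, k) i + nx * ((j - 1L) + ny * (k - 1L))
  ii <- jj <- xx <- vector("list", 7)
  gi <- rep(seq_len(nx), times = ny * nz)
  gj <- rep(rep(seq_len(ny), each = nx), times = nz)
  gk <- rep(seq_len(nz), each = nx * ny)
  id <- seq_len(N)
  diagc <- numeric(N)
  off_i <- integer(0); off_j <- integer(0)
  for (ax in 1:3) {
    gc <- switch(ax, gi, gj, gk)
    nc <- n[ax]
    stride <- c(1L, nx, nx * ny)[ax]
    # low side
    has_lo <- gc > 1L
    diagc <- diagc + ifelse(has_lo, 1, 2)
    off_i <- c(off_i, id[has_lo]); off_j <- c(off_j, id[has_lo] - stride)
    # high side
    has_hi <- gc < nc
    diagc <- diagc + ifelse(has_hi, 1, 2)
    off_i <- c(off_i, id[has_hi]); off_j <- c(off_j, id[has_hi] + stride)
  }
  h2 <- grid$h^2
  A <- Matrix::sparseMatrix(
    i = c(id, off_i), j = c(id, off_j),
    x = c(diagc, rep(-1, length(off_i))) / h2,
    dims = c(N, N))
  A <- Matrix::forceSymmetric(A)
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  grid$cache$chol <- ch
  ch
}

## boundary-pressure contribution to the Poisson RHS: Dirichlet ghost cells
## add 2 p_b / h^2 on boundary-adjacent cells
pbc_rhs <- function(grid, state) {
  n <- grid$n
  pbc <- state$pbc
  r <- array(0, n)
  c2 <- 2 / grid$h^2
  r[1, , ]      <- r[1, , ]      + c2 * pbc[1]
  r[n[1], , ]   <- r[n[1], , ]   + c2 * pbc[2]
  r[, 1, ]      <- r[, 1, ]      + c2 * pbc[3]
  r[, n[2], ]   <- r[, n[2], ]   + c2 * pbc[4]
  r[, , 1]      <- r[, , 1]      + c2 * state$pz0
  r[, , n[3]]   <- r[, , n[3]]   + c2 * state$pz1
  r
}

#' Pressure projection
#'
#' Projects the velocity onto the divergence-free space: solves
#' `lap p = (rho/dt) div u` with the boundary pressures of the state as
#' Dirichlet ghost-cell values (which both fixes the pressure gauge and
#' drives the flow), then corrects `u <- u - (dt/rho) grad p`.  A sparse
#' Cholesky factorisation of the Poisson operator is built once per grid
#' and cached; periodic test grids use an FFT solve instead.
#'
#' @param state a [fluid_state] holding the intermediate velocity.
#' @param dt time step used in the pressure scaling (s).
#' @param tol relative bound on the post-projection divergence:
#'   `max |div u| <= tol * max(|u|, u_floor) / h`.
#' @param u_floor velocity scale floor (cm/s) for the relative tolerance.
#' @param check verify the post-projection divergence (costs one extra
#'   divergence evaluation; inner loops verify periodically instead).
#' @return State with divergence-free velocity and updated pressure.
#' @export
project <- function(state, dt = 1, tol = 1e-8, u_floor = 1e-8,
                    check = TRUE) {
  g <- state$grid
  u_in <- max_speed(state)
  dv <- divergence(state)
  if (g$periodic) {
    p <- fft_poisson(dv * state$rho / dt, g)
  } else {
    ch <- poisson_factor(g)
    rhs <- -(dv * state$rho / dt) + pbc_rhs(g, state)
    p <- array(as.numeric(Matrix::solve(ch, as.vector(rhs))), g$n)
  }
  res <- cpp_grad_correct(state$u, state$v, state$w, p,
                          g$n[1], g$n[2], g$n[3], g$h, dt / state$rho,
                          state$pbc, state$pz0, state$pz1, g$periodic)
  state$u <- array(res$u, stag_dims(g, "u"))
  state$v <- array(res$v, stag_dims(g, "v"))
  state$w <- array(res$w, stag_dims(g, "w"))
  state$p <- p
  if (check) {
    resid <- max(abs(divergence(state)))
    bound <- tol * max(max_speed(state), u_in, u_floor) / g$h
    if (resid > bound)
      stop("projection failed to reach tolerance: |div u| = ",
           signif(resid, 4), " > ", signif(bound, 4))
  }
  state
}

## spectral Poisson solve, periodic box: lap p = rhs (zero-mean gauge)
fft_poisson <- function(rhs, grid) {
  n <- grid$n; h <- grid$h
  lam <- function(m) (2 * cos(2 * pi * (seq_len(m) - 1) / m) - 2) / h^2
  lx <- lam(n[1]); ly <- lam(n[2]); lz <- lam(n[3])
  den <- outer(outer(lx, ly, `+`), lz, `+`)
  den[1, 1, 1] <- 1
  ph <- fft(rhs) / den
  ph[1, 1, 1] <- 0
  Re(fft(ph, inverse = TRUE)) / prod(n)
}
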