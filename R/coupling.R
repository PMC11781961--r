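#' Regularised delta-function kernel specification
#'
#' The discrete Dirac delta used for force spreading and velocity
#' interpolation between the Lagrangian mesh and the Eulerian grid.
#' Families: `"ib4"` (Peskin 4-point, default), `"ib3"` (Peskin 3-point)
#' and `"ib6"` (quintic B-spline, 6-point support).  All satisfy the
#' partition-of-unity identity \eqn{\sum_j \phi(r-j) = 1} and the zero
#' first-moment identity \eqn{\sum_j (r-j)\phi(r-j) = 0} for every offset
#' `r`, which make interpolation exact for constant and linear fields and
#' spreading conservative.
#'
#' @param family kernel family name.
#' @return An `ib_kernel` object with the support width in cells.
#' @export
ib_kernel <- function(family = c("ib4", "ib3", "ib6")) {
  family <- match.arg(family)
  width <- c(ib3 = 3L, ib4 = 4L, ib6 = 6L)[[family]]
  structure(list(family = family, width = width,
                 code = as.integer(sub("ib", "", family))),
            class = "ib_kernel")
}

#' One-dimensional kernel weights
#'
#' Weights of the regularised delta over its support for a point at offset
#' `r` (in cells) from the grid line `0`.
#'
#' @param r scalar offset in cell units.
#' @param kernel an [ib_kernel].
#' @return Named numeric vector of weights; names are the integer grid
#'   offsets of the support window.
#' @export
kernel_weights <- function(r, kernel = ib_kernel()) {
  if (!is.finite(r)) stop("offset must be finite")
  half <- kernel$width / 2
  j0 <- if (kernel$width %% 2L == 1L) floor(r + 0.5) - (kernel$width - 1L) / 2
        else floor(r) - (half - 1L)
  j <- j0 + seq_len(kernel$width) - 1
  w <- cpp_kernel_phi(r - j, kernel$code)
  names(w) <- j
  w
}

node_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("positions must be an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}

#' Spread Lagrangian forces to the Eulerian grid
#'
#' Discretises \eqn{f(x) = \int F(X) \delta(x - \chi(X)) dX} with lumped
#' nodal quadrature: each node contributes its force density times its
#' reference volume weight, distributed over the kernel support of the
#' matching staggered component.  Total force is conserved:
#' \eqn{h^3 \sum f = \sum F w}.
#'
#' @param positions n x 3 current node positions (cm).
#' @param forces n x 3 nodal force densities (dyn/cm^3 of reference volume).
#' @param weights length-n nodal reference volumes (cm^3).
#' @param state a [fluid_state]; its body force is overwritten.
#' @param kernel an [ib_kernel].
#' @param accumulate logical; add to the existing body force instead of
#'   replacing it.
#' @param warn warn when kernel supports are clamped at the domain
#'   boundary.
#' @return The fluid state with `fx`, `fy`, `fz` set (dyn/cm^3).
#' @export
ib_spread <- function(positions, forces, weights, state,
                      kernel = ib_kernel(), accumulate = FALSE,
                      warn = TRUE) {
  g <- state$grid
  pos <- node_matrix(positions)
  q <- node_matrix(forces) * as.numeric(weights)
  res <- cpp_spread(pos, q, g$n[1], g$n[2], g$n[3], g$h,
                    kernel$code, g$periodic)
  if (warn && res$n_clamped > 0L)
    warning(res$n_clamped, " node(s) within kernel support of the domain ",
            "boundary; support clamped")
  fx <- array(res$fx, stag_dims(g, "u"))
  fy <- array(res$fy, stag_dims(g, "v"))
  fz <- array(res$fz, stag_dims(g, "w"))
  if (accumulate) {
    state$fx <- state$fx + fx; state$fy <- state$fy + fy
    state$fz <- state$fz + fz
  } else {
    state$fx <- fx; state$fy <- fy; state$fz <- fz
  }
  state
}

#' Interpolate the Eulerian velocity to Lagrangian points
#'
#' Discretises \eqn{U(X) = \int u(x) \delta(x - \chi(X)) dx} componentwise
#' on the staggered grids.  Exact for constant and linear velocity fields
#' (partition-of-unity and first-moment identities).
#'
#' @param state a [fluid_state].
#' @param positions n x 3 node positions (cm).
#' @param kernel an [ib_kernel].
#' @param warn warn when kernel supports are clamped at the domain
#'   boundary.
#' @return n x 3 matrix of node velocities (cm/s).
#' @export
ib_interpolate <- function(state, positions, kernel = ib_kernel(),
                           warn = TRUE) {
  g <- state$grid
  pos <- node_matrix(positions)
  res <- cpp_interp(state$u, state$v, state$w, pos,
                    g$n[1], g$n[2], g$n[3], g$h, kernel$code, g$periodic)
  if (warn && res$n_clamped > 0L)
    warning(res$n_clamped, " node(s) within kernel support of the domain ",
            "boundary; support clamped")
  res$U
}
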