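#' Deformation gradient of a linear tetrahedron
#'
#' For linear tetrahedra the deformation gradient is constant per element:
#' it maps reference edge vectors onto current edge vectors,
#' `F = D_cur D_ref^{-1}`.
#'
#' @param ref_nodes 4 x 3 reference vertex coordinates (cm).
#' @param cur_nodes 4 x 3 current vertex coordinates (cm).
#' @return 3 x 3 deformation gradient.
#' @export
element_deformation_gradient <- function(ref_nodes, cur_nodes) {
  ref <- as.matrix(ref_nodes); cur <- as.matrix(cur_nodes)
  Dref <- t(ref[2:4, , drop = FALSE]) - ref[1, ]
  if (abs(det(Dref)) < 1e-14 * max(abs(Dref))^3 || det(Dref) == 0)
    stop("degenerate reference element (zero volume)")
  Dcur <- t(cur[2:4, , drop = FALSE]) - cur[1, ]
  Dcur %*% solve(Dref)
}

## Per-element shape-function gradients and signed volumes, plus the
## node -> element scatter operator and lumped nodal reference volumes.
## Cached on the mesh environment by fe_precompute().
fe_precompute <- function(mesh) {
  if (!is.null(mesh$cache$fe)) return(mesh$cache$fe)
  conn <- mesh$elements
  ne <- nrow(conn)
  X <- mesh$nodes
  e1 <- X[conn[, 2], , drop = FALSE] - X[conn[, 1], , drop = FALSE]
  e2 <- X[conn[, 3], , drop = FALSE] - X[conn[, 1], , drop = FALSE]
  e3 <- X[conn[, 4], , drop = FALSE] - X[conn[, 1], , drop = FALSE]
  detD <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
          e2[, 1] * (e1[, 2] * e3[, 3] - e1[, 3] * e3[, 2]) +
          e3[, 1] * (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])
  vol <- detD / 6
  if (any(vol <= 0))
    stop("inverted or degenerate reference element(s): ",
         paste(utils::head(which(vol <= 0), 10), collapse = ", "))
  ## rows of D^{-1} (gradients of the barycentric shape functions 2..4):
  ## D^{-1} = adj(D)/det, adj = cofactor transpose; D columns are e1,e2,e3
  inv <- array(0, c(ne, 3, 3))           # inv[, r, c] = (D^{-1})_{rc}
  inv[, 1, 1] <- (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) / detD
  inv[, 1, 2] <- (e3[, 1] * e2[, 3] - e2[, 1] * e3[, 3]) / detD
  inv[, 1, 3] <- (e2[, 1] * e3[, 2] - e3[, 1] * e2[, 2]) / detD
  inv[, 2, 1] <- (e3[, 2] * e1[, 3] - e1[, 2] * e3[, 3]) / detD
  inv[, 2, 2] <- (e1[, 1] * e3[, 3] - e3[, 1] * e1[, 3]) / detD
  inv[, 2, 3] <- (e3[, 1] * e1[, 2] - e1[, 1] * e3[, 2]) / detD
  inv[, 3, 1] <- (e1[, 2] * e2[, 3] - e2[, 2] * e1[, 3]) / detD
  inv[, 3, 2] <- (e2[, 1] * e1[, 3] - e1[, 1] * e2[, 3]) / detD
  inv[, 3, 3] <- (e1[, 1] * e2[, 2] - e2[, 1] * e1[, 2]) / detD
  gn <- array(0, c(ne, 4, 3))            # gn[, a, j] = dN_a/dX_j
  gn[, 2, ] <- inv[, 1, ]
  gn[, 3, ] <- inv[, 2, ]
  gn[, 4, ] <- inv[, 3, ]
  gn[, 1, ] <- -(gn[, 2, ] + gn[, 3, ] + gn[, 4, ])
  scatter <- Matrix::sparseMatrix(i = as.vector(conn),
                                  j = seq_len(4L * ne), x = 1,
                                  dims = c(nrow(X), 4L * ne))
  nodal_vol <- as.numeric(scatter %*% rep(vol / 4, 4))
  ## cache-friendly layouts for the C++ assembly: gradients and
  ## connectivity contiguous per element
  gradNt <- as.numeric(aperm(gn, c(2, 3, 1)))
  connt <- t(conn)
  storage.mode(connt) <- "integer"
  fe <- list(gradN = gn, vol = vol, scatter = scatter,
             nodal_vol = nodal_vol, gradNt = gradNt, connt = connt)
  mesh$cache$fe <- fe
  fe
}

## batch deformation gradients: returns ne x 9 (column-major tensor rows)
fe_deformation_gradients <- function(mesh, x) {
  fe <- fe_precompute(mesh)
  conn <- mesh$elements
  gn <- fe$gradN
  F <- matrix(0, nrow(conn), 9L)
  for (i in 1:3) {
    xi <- matrix(x[conn, i], nrow(conn), 4L)
    for (j in 1:3) {
      F[, i + 3L * (j - 1L)] <-
        xi[, 1] * gn[, 1, j] + xi[, 2] * gn[, 2, j] +
        xi[, 3] * gn[, 3, j] + xi[, 4] * gn[, 4, j]
    }
  }
  F
}

#' Assemble weak-form internal elastic forces
#'
#' Evaluates the Lagrangian elastic force density from the weak form
#' \eqn{\int_U F_L \cdot V \, dX = -\int_U P : \nabla_X V \, dX} with
#' one-point quadrature on linear tetrahedra and a lumped reference-volume
#' mass matrix: the load vector of each FE basis function is divided by the
#' lumped nodal reference volume, giving a force per unit reference volume
#' suitable for delta-function spreading.
#'
#' @param mesh a [structural_mesh].
#' @param x n x 3 current node positions (cm).
#' @param materials named list of [material_params] for regions
#'   `wall`, `sinus`, `leaflet` (kPa; converted internally to CGS,
#'   1 kPa = 1e4 dyn/cm^2).
#' @param xdot optional n x 3 node velocities (cm/s) for the viscous
#'   stress.
#' @param eta Kelvin--Voigt damping coefficient (kPa s); adds a viscous
#'   stress `eta * dF/dt` that suppresses under-damped high-frequency
#'   tissue ringing at coarse resolutions (0 = purely hyperelastic).
#' @param exp_cap upper bound on the exponential stiffening argument
#'   `c3 (I1 - 3)^2` of the exponential model form (default `Inf`, the
#'   exact material).  Coarse presets use a finite cap as a tangent
#'   stiffness limiter: it leaves the response exact for all strains below
#'   `sqrt(exp_cap / c3)` -- far above the physiological static strains --
#'   and only bounds the feedback gain of spurious coarse-grid
#'   excursions.
#' @return List with `force_density` (n x 3, dyn/cm^3), `force`
#'   (n x 3, dyn: load vector), `F` (ne x 9 per-element deformation
#'   gradients) and `energy` (total strain energy, erg).
#' @export
assemble_internal_forces <- function(mesh, x, materials = default_materials(),
                                     xdot = NULL, eta = 0, exp_cap = Inf) {
  fe <- fe_precompute(mesh)
  x <- node_matrix(x)
  mp <- element_materials(mesh, materials)
  res <- cpp_fe_forces(t(x), fe$connt, fe$gradNt, fe$vol,
                       mp$model, mp$ca, mp$cb, mp$beta,
                       xdot = if (is.null(xdot)) NULL else t(xdot),
                       eta = eta, exp_cap = exp_cap)
  force <- t(res$force)
  list(force_density = force / fe$nodal_vol, force = force,
       F = res$F, energy = res$energy)
}

## per-element material coefficient vectors (cached per material set)
element_materials <- function(mesh, materials) {
  key <- paste(vapply(c("wall", "sinus", "leaflet"), function(r) {
    m <- materials[[r]]
    if (is.null(m)) stop("no material parameters for region '", r, "'")
    paste(m$model_form,
          paste(unlist(m[setdiff(names(m), "model_form")]), collapse = ","))
  }, character(1)), collapse = ";")
  cached <- mesh$cache$mats
  if (!is.null(cached) && identical(cached$key, key)) return(cached)
  ne <- nrow(mesh$elements)
  model <- integer(ne); ca <- numeric(ne); cb <- numeric(ne)
  beta <- numeric(ne)
  for (reg in c("wall", "sinus", "leaflet")) {
    sel <- mesh$region == reg
    m <- materials[[reg]]
    if (m$model_form == "polynomial") {
      model[sel] <- 0L; ca[sel] <- m$c0; cb[sel] <- m$c1
    } else {
      model[sel] <- 1L; ca[sel] <- m$c2; cb[sel] <- m$c3
    }
    beta[sel] <- m$beta
  }
  out <- list(key = key, model = model, ca = ca, cb = cb, beta = beta)
  mesh$cache$mats <- out
  out
}

#' Implicit Lagrangian velocity smoothing operator
#'
#' Assembles the scalar viscous operator `B` with entries
#' `B_ab = sum_e eta_e V_e grad(N_a) . grad(N_b)` and the lumped reference
#' mass `M = diag(nodal volumes)`, and factorises `M + dt B`.  Applying
#' `(M + dt B)^{-1} M` to the interpolated node velocities damps
#' sub-element-scale relative motion of the Lagrangian mesh
#' unconditionally (backward-Euler treatment of a Kelvin--Voigt-type
#' viscosity acting on the velocity field), while leaving smooth rigid and
#' low-frequency motion essentially untouched.
#'
#' @param mesh a [structural_mesh].
#' @param eta viscosity (poise-like, g/(cm s)); scalar or per-element.
#' @param dt time step (s).
#' @return A solver closure: `function(U)` smoothing an n x 3 velocity
#'   matrix.
#' @export
velocity_smoother <- function(mesh, eta, dt) {
  fe <- fe_precompute(mesh)
  key <- paste(eta[1], dt)
  cached <- mesh$cache$smoother
  if (!is.null(cached) && identical(cached$key, key)) return(cached$fun)
  conn <- mesh$elements
  ne <- nrow(conn)
  eta <- rep_len(eta, ne)
  gn <- fe$gradN
  ii <- jj <- xx <- vector("list", 16L)
  m <- 0L
  for (a in 1:4) for (b in 1:4) {
    m <- m + 1L
    ii[[m]] <- conn[, a]
    jj[[m]] <- conn[, b]
    xx[[m]] <- eta * fe$vol *
      (gn[, a, 1] * gn[, b, 1] + gn[, a, 2] * gn[, b, 2] +
       gn[, a, 3] * gn[, b, 3])
  }
  B <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = rep(nrow(mesh$nodes), 2))
  A <- Matrix::forceSymmetric(
    Matrix::Diagonal(x = fe$nodal_vol) + dt * B)
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  M <- fe$nodal_vol
  fun <- function(U) as.matrix(Matrix::solve(ch, U * M))
  mesh$cache$smoother <- list(key = key, fun = fun)
  fun
}

#' Penalty tether forces on the fixed vein ends
#'
#' The vein end rings are held by stiff linear springs to their reference
#' positions (standard IB practice for "fixed" boundaries): force density
#' `kappa * (X - x)` on fixed nodes, zero elsewhere.
#'
#' @param mesh a [structural_mesh].
#' @param x n x 3 current node positions (cm).
#' @param kappa spring stiffness per unit reference volume and displacement
#'   (dyn/cm^3 per cm).
#' @return n x 3 force densities (dyn/cm^3).
#' @export
tether_forces <- function(mesh, x, kappa) {
  if (kappa < 0) stop("'kappa' must be non-negative")
  f <- matrix(0, nrow(mesh$nodes), 3L)
  idx <- mesh$fixed
  f[idx, ] <- kappa * (mesh$nodes[idx, , drop = FALSE] -
                       x[idx, , drop = FALSE])
  f
}
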