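test_that("element deformation gradients reproduce affine maps", {
  ref <- unit_tet()
  expect_equal(element_deformation_gradient(ref, ref), diag(3))
  expect_equal(element_deformation_gradient(ref, 2 * ref), 2 * diag(3))
  set.seed(41)
  R <- random_rotation()
  F <- element_deformation_gradient(ref, t(R %*% t(ref)))
  expect_equal(F, R, tolerance = 1e-12)
  expect_equal(det(F), 1, tolerance = 1e-12)
  # degenerate reference element
  bad <- ref; bad[4, ] <- ref[1, ]
  expect_error(element_deformation_gradient(bad, bad), "degenerate")
})

## small structured block meshed with the same Freudenthal rule as the
## package mesher, used for patch and convergence checks
block_mesh <- function(n, L = 1) {
  xs <- seq(0, L, length.out = n + 1)
  idx <- function(i, j, k) i + (n + 1) * ((j - 1) + (n + 1) * (k - 1))
  nodes <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  hexes <- list()
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    v <- c(idx(i, j, k), idx(i + 1, j, k), idx(i, j + 1, k),
           idx(i + 1, j + 1, k), idx(i, j, k + 1), idx(i + 1, j, k + 1),
           idx(i, j + 1, k + 1), idx(i + 1, j + 1, k + 1))
    hexes[[length(hexes) + 1]] <- v
  }
  elements <- valvefsi:::split_hexes(do.call(rbind, hexes))
  v <- valvefsi:::tet_volumes(nodes, elements)
  elements[v < 0, 3:4] <- elements[v < 0, 4:3]
  mesh <- list(nodes = nodes, elements = elements,
               region = rep("leaflet", nrow(elements)),
               fixed = integer(0), free_edges = list(integer(0), integer(0)),
               params = NULL, resolution = L / n,
               cache = new.env(parent = emptyenv()))
  class(mesh) <- "structural_mesh"
  mesh
}

test_that("internal forces vanish for the reference and rigid motions", {
  mesh <- block_mesh(3)
  out <- assemble_internal_forces(mesh, mesh$nodes)
  expect_lt(max(abs(out$force)), 1e-12)
  set.seed(42)
  R <- random_rotation()
  xr <- t(R %*% t(mesh$nodes)) + rep(c(0.2, -0.1, 0.3), each = nrow(mesh$nodes))
  outr <- assemble_internal_forces(mesh, xr)
  # round-off scale: stresses are ~1e4 dyn/cm^2 per unit coefficient
  expect_lt(max(abs(outr$force)), 1e-8)
})

test_that("internal forces obey Newton's third law under any deformation", {
  mesh <- block_mesh(3)
  set.seed(43)
  x <- mesh$nodes + 0.05 * matrix(rnorm(length(mesh$nodes)), ncol = 3)
  out <- assemble_internal_forces(mesh, x)
  expect_lt(max(abs(colSums(out$force))), 1e-8 * max(abs(out$force)))
})

test_that("single-element loads match the constant-stress face-traction oracle", {
  ref <- unit_tet()
  mesh <- list(nodes = ref, elements = matrix(1:4, 1), region = "leaflet",
               fixed = integer(0), free_edges = list(integer(0), integer(0)),
               params = NULL, resolution = 1,
               cache = new.env(parent = emptyenv()))
  class(mesh) <- "structural_mesh"
  lam <- 1.3
  x <- ref %*% diag(c(lam, 1, 1))
  mats <- default_materials()
  out <- assemble_internal_forces(mesh, x, mats)
  # oracle: for constant P, the weak-form load on node a equals
  # (1/3) P . (area vector of the face opposite a), via the identity
  # V grad(N_a) = -(1/3) A_a n_a
  P <- pk1_stress(mats$leaflet, diag(c(lam, 1, 1))) * 1e4
  others <- list(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  for (a in 1:4) {
    tri <- ref[others[[a]], ]
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    nvec <- 0.5 * cr(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    # ensure outward orientation (away from node a)
    if (sum(nvec * (colMeans(tri) - ref[a, ])) < 0) nvec <- -nvec
    expect_equal(out$force[a, ], as.numeric(P %*% nvec) / 3,
                 tolerance = 1e-9)
  }
})

test_that("a uniformly strained block reproduces the single-element state", {
  mesh <- block_mesh(3)
  F <- diag(3) + matrix(c(0.02, 0.01, 0, 0.005, -0.01, 0, 0, 0.02, 0.015),
                        3, 3)
  x <- mesh$nodes %*% t(F)
  out <- assemble_internal_forces(mesh, x)
  Fel <- matrix(out$F[10, ], 3, 3)
  expect_equal(Fel, F, tolerance = 1e-12)
  # interior nodes of a uniform-stress patch carry no net force
  interior <- which(apply(mesh$nodes, 1, function(p)
    all(p > 1 / 3 - 1e-9 & p < 2 / 3 + 1e-9)))
  expect_gt(length(interior), 0)
  expect_lt(max(abs(out$force[interior, ])),
            1e-10 * max(abs(out$force)))
})

test_that("strain energy converges under mesh refinement", {
  # smooth incompressible-ish deformation x = X + a sin(pi X) applied to
  # a unit cube; energy from refined meshes must approach the fine value
  defo <- function(X) X + 0.03 * sin(pi * X[, c(2, 3, 1)])
  en <- vapply(c(3, 6, 12), function(n) {
    mesh <- block_mesh(n)
    assemble_internal_forces(mesh, defo(mesh$nodes))$energy
  }, numeric(1))
  err <- abs(en[1:2] - en[3])
  expect_lt(err[2], 0.6 * err[1])   # at least first-order decrease
})

test_that("tether forces are linear springs on the fixed set only", {
  mesh <- block_mesh(2)
  mesh$fixed <- c(1L, 5L)
  x <- mesh$nodes
  expect_identical(max(abs(tether_forces(mesh, x, 100))), 0)
  x[1, ] <- x[1, ] + c(0.01, 0, 0)
  f <- tether_forces(mesh, x, 100)
  expect_equal(f[1, ], c(-1, 0, 0))
  expect_identical(max(abs(f[-1, ])), 0)
  expect_equal(tether_forces(mesh, x, 200)[1, ], 2 * f[1, ])
  expect_error(tether_forces(mesh, x, -1), "non-negative")
})

test_that("velocity smoothing preserves rigid motion and damps noise", {
  mesh <- block_mesh(4)
  sm <- velocity_smoother(mesh, eta = 10, dt = 1e-4)
  U <- matrix(rep(c(1, -2, 0.5), each = nrow(mesh$nodes)), ncol = 3)
  expect_equal(sm(U), U, tolerance = 1e-9, ignore_attr = TRUE)
  set.seed(9)
  noise <- matrix(rnorm(length(U)), ncol = 3)
  expect_lt(sd(sm(noise)), sd(noise))
})
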