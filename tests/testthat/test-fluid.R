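test_that("MAC divergence stencil is exact for constant and linear fields", {
  g <- fluid_grid(c(8, 8, 8), c(1, 1, 1))
  s <- fluid_state(g)
  expect_equal(max(abs(divergence(s))), 0)
  # u = x sampled on x-faces -> div = 1 exactly
  xf <- (0:8) * g$h
  s$u <- array(rep(xf, 64), c(9, 8, 8))
  expect_equal(as.vector(divergence(s)), rep(1, 512), tolerance = 1e-13)
  # u = (x, -y, 0) -> 0 exactly
  yf <- (0:8) * g$h
  s$v <- aperm(array(rep(-yf, 64), c(9, 8, 8)), c(2, 1, 3))
  expect_lt(max(abs(divergence(s))), 1e-13)
})

test_that("projection annihilates discrete gradient fields (periodic)", {
  g <- fluid_grid(c(16, 16, 16), c(1, 1, 1), periodic = TRUE)
  s <- fluid_state(g)
  set.seed(31)
  phi <- array(rnorm(16^3), c(16, 16, 16))
  # low-pass the potential so it is smooth-ish (not required, but realistic)
  gradx <- (phi - phi[c(16, 1:15), , ]) / g$h
  grady <- (phi - phi[, c(16, 1:15), ]) / g$h
  gradz <- (phi - phi[, , c(16, 1:15)]) / g$h
  s$u <- gradx; s$v <- grady; s$w <- gradz
  s2 <- project(s, dt = 0.01)
  expect_lt(max(abs(s2$u), abs(s2$v), abs(s2$w)), 1e-10)
})

test_that("projection reaches tolerance and is idempotent", {
  g <- fluid_grid(c(16, 16, 16), c(1, 1, 1), periodic = TRUE)
  s <- fluid_state(g)
  set.seed(32)
  s$u <- array(rnorm(16^3), c(16, 16, 16))
  s$v <- array(rnorm(16^3), c(16, 16, 16))
  s$w <- array(rnorm(16^3), c(16, 16, 16))
  s2 <- project(s, dt = 0.1)
  expect_lt(max(abs(divergence(s2))),
            1e-8 * max(abs(c(s2$u, s2$v, s2$w))) / g$h)
  s3 <- project(s2, dt = 0.1)
  expect_equal(s3$u, s2$u, tolerance = 1e-12)
})

test_that("boundary pressures drive flow in the right direction", {
  g <- fluid_grid(c(8, 8, 24), c(1, 1, 3))
  s <- fluid_state(g)
  # balanced pressures: no net axial momentum beyond the symmetric
  # equilibration transient
  s1 <- apply_pressure_bcs(s, 5332.9, 5332.9)
  s1 <- project(s1, dt = 1e-3)
  expect_lt(abs(sum(s1$w)), 1e-8 * max(abs(s1$w), 1e-30) * length(s1$w))
  # forward difference of 1 mmHg: positive axial momentum develops
  s2 <- apply_pressure_bcs(s, 1333.22, 0)
  s2 <- project(s2, dt = 1e-3)
  expect_gt(mean(s2$w), 0)
  expect_lt(max(abs(divergence(s2))), 1e-6)
})

test_that("advection-diffusion preserves rest and uniform states", {
  g <- fluid_grid(c(8, 8, 8), c(1, 1, 1), periodic = TRUE)
  s <- fluid_state(g)
  s2 <- advect_diffuse(s, 1e-4)
  expect_identical(max(abs(s2$u)), 0)
  s$u[] <- 2; s$v[] <- -1; s$w[] <- 0.5
  s3 <- advect_diffuse(s, 1e-4)
  expect_equal(s3$u, s$u, tolerance = 1e-14)
  expect_equal(s3$w, s$w, tolerance = 1e-14)
})

test_that("single-mode diffusion decays at the discrete heat-equation rate", {
  n <- 32
  g <- fluid_grid(c(n, n, n), c(1, 1, 1), periodic = TRUE)
  s <- fluid_state(g)
  yc <- ((1:n) - 0.5) * g$h
  kwav <- 2 * pi
  s$u <- aperm(array(rep(sin(kwav * yc), n * n), c(n, n, n)), c(2, 1, 3))
  nu <- s$mu / s$rho
  dt <- 0.2 * g$h^2 * s$rho / (6 * s$mu)
  s2 <- advect_diffuse(s, dt)
  ratio <- max(abs(s2$u)) / max(abs(s$u))
  k2_disc <- (2 - 2 * cos(kwav * g$h)) / g$h^2
  # forward-Euler amplification matches exp(-nu k^2 dt) to O(dt^2)
  expect_equal(ratio, 1 - nu * k2_disc * dt, tolerance = 1e-12)
  expect_lt(abs(ratio - exp(-nu * k2_disc * dt)), 10 * (nu * k2_disc * dt)^2)
})

test_that("the explicit stability bound is enforced with a suggestion", {
  g <- fluid_grid(c(8, 8, 8), c(1, 1, 1))
  s <- fluid_state(g)
  s$u[] <- 100
  expect_error(advect_diffuse(s, 1), "use dt <=")
})

test_that("uniform body force accelerates a periodic box at f/rho", {
  g <- fluid_grid(c(8, 8, 8), c(1, 1, 1), periodic = TRUE)
  s <- fluid_state(g)
  s$fz[] <- 10
  dt <- 1e-4
  for (i in 1:5) s <- advect_diffuse(s, dt)
  expect_equal(mean(s$w), 10 / s$rho * 5 * dt, tolerance = 1e-12)
})
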