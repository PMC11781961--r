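test_that("GOA reproduces the ellipse formula and the closed state", {
  th <- seq(0, pi, length.out = 21)   # includes the apex at pi/2
  # two half-circles of diameter 0.4 -> equal axes
  e1 <- cbind(0.2 * cos(th), 0.2 * sin(th), 0)
  e2 <- cbind(0.2 * cos(th), -0.2 * sin(th), 0)
  expect_equal(geometric_orifice_area(e1, e2), pi / 4 * 0.4 * 0.4,
               tolerance = 1e-9)
  # unequal axes 0.6 x 0.2
  e1 <- cbind(0.3 * cos(th), 0.1 * sin(th), 0)
  e2 <- cbind(0.3 * cos(th), -0.1 * sin(th), 0)
  expect_equal(geometric_orifice_area(e1, e2), pi / 4 * 0.6 * 0.2,
               tolerance = 1e-9)
  # contact within tolerance -> closed
  e1c <- e1; e1c[, 2] <- e1c[, 2] * 0.001
  e2c <- cbind(0.3 * cos(th), 0.0004 - 0.0008 * sin(th), 0)
  expect_identical(geometric_orifice_area(e1c, e2c, closed_tol = 1e-3), 0)
  expect_error(geometric_orifice_area(e1[1:4, ], e2), "at least 8")
})

test_that("transvalvular flow rate integrates masked axial velocity", {
  g <- fluid_grid(c(48, 48, 8), c(1, 1, 1 / 6))
  s <- fluid_state(g)
  R <- 0.3455
  xc <- (seq_len(48) - 0.5) * g$h - 0.5
  mask <- outer(xc, xc, function(a, b) a^2 + b^2) < R^2
  s$w[] <- 1
  Q <- transvalvular_flow_rate(s, plane_z = 0.08, mask = mask)
  expect_equal(Q, pi * R^2, tolerance = 0.02)
  expect_identical(transvalvular_flow_rate(fluid_state(g), 0.08, mask), 0)
  s$w[] <- -1
  expect_lt(transvalvular_flow_rate(s, 0.08, mask), 0)
  expect_error(transvalvular_flow_rate(s, 5, mask), "outside")
})

test_that("stagnant fraction counts sub-threshold cells", {
  g <- fluid_grid(c(8, 8, 8), c(1, 1, 1))
  s <- fluid_state(g)
  mask <- array(TRUE, c(8, 8, 8))
  expect_equal(stagnant_fraction(s, mask), 1)
  s$u[] <- 2
  expect_equal(stagnant_fraction(s, mask), 0)
  s$u[] <- 0
  # cells 1-4 average below threshold, cells 5-8 above
  s$w[, , 1:4] <- 0.5; s$w[, , 5] <- 1.0; s$w[, , 6:9] <- 1.5
  expect_equal(stagnant_fraction(s, mask), 0.5)
  expect_error(stagnant_fraction(s, mask & FALSE), "empty mask")
})

test_that("dilation ratio tracks uniform radial expansion", {
  p <- geometry_params()
  mesh <- build_structural_mesh(p, 0.06)
  expect_equal(dilation_ratio(mesh, mesh$nodes, measurement_z = 0.3), 1)
  x <- mesh$nodes
  x[, 1:2] <- x[, 1:2] * 1.10
  expect_equal(dilation_ratio(mesh, x, measurement_z = 0.3), 1.10,
               tolerance = 1e-9)
  expect_warning(dilation_ratio(mesh, x, measurement_z = p$valve_z),
                 "sinus")
})

test_that("phase segmentation recovers trapezoid fractions exactly", {
  t <- seq(0, 0.999, by = 0.001)
  goa <- ifelse(t < 0.15, t / 0.15,
         ifelse(t < 0.45, 1,
         ifelse(t < 0.65, (0.65 - t) / 0.2, 0))) * 0.1
  seg <- segment_phases(t, goa)
  expect_equal(seg$fraction[match(c("opening", "equilibrium", "closing",
                                    "closed"), seg$phase)],
               c(0.15, 0.30, 0.20, 0.35), tolerance = 1e-6)
  expect_warning(s0 <- segment_phases(t, rep(0, length(t))), "never opens")
  expect_equal(s0$fraction, 1)
  expect_warning(s1 <- segment_phases(t, rep(0.1, length(t))),
                 "never closes")
  expect_identical(as.character(s1$phase), "equilibrium")
})

test_that("velocity profiles recover an imposed Poiseuille field", {
  p <- geometry_params(l = 3, valve_z = 1.5)
  g <- fluid_grid(c(32, 32, 96), c(1, 1, 3))
  s <- fluid_state(g)
  R <- p$d / 2
  umax <- 30
  xc <- (seq_len(32) - 0.5) * g$h - 0.5
  r2 <- outer(xc, xc, function(a, b) a^2 + b^2)
  prof <- pmax(0, umax * (1 - r2 / R^2))
  s$w <- array(rep(prof, 97), c(32, 32, 97))
  # the imposed field is exactly quadratic; lm warns about a perfect fit
  out <- suppressWarnings(axial_velocity_profiles(s, p))
  expect_length(out, 5)
  for (st in out[c("A", "E")]) {
    expect_gt(attr(st, "r2"), 0.98)
    expect_equal(attr(st, "fit_peak"), umax, tolerance = 0.02)
  }
  # zero field -> all-zero profiles
  s0 <- fluid_state(g)
  out0 <- axial_velocity_profiles(s0, p)
  expect_identical(max(abs(out0$A$speed)), 0)
  expect_error(axial_velocity_profiles(s, p, stations = 10), "outside")
})
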