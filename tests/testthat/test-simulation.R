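test_that("the driving pressure protocol matches its definition", {
  sp <- pressure_profile()        # A = 0.5, P0 = 4, T = 1 s
  # peak forward difference at quarter cycle
  p <- inlet_outlet_pressures(0.25, sp)
  expect_equal(unname(p[1, ]), c(4.5, 4.0))
  # zero difference at cycle start (after the hydrostatic start-up)
  p0 <- inlet_outlet_pressures(2, sp)
  expect_equal(unname(p0[1, "p_in"] - p0[1, "p_out"]), 0, tolerance = 1e-12)
  # closing dip in the final tenth of the cycle
  pd <- inlet_outlet_pressures(0.95, sp)
  expect_equal(unname(pd[1, "p_in"] - pd[1, "p_out"]), -0.05)
  # the difference is continuous across the piece boundaries
  ts <- c(0.5, 0.9, 0.905, 0.995, 1)
  for (tb in ts) {
    lo <- inlet_outlet_pressures(tb - 1e-9 + 1, sp)
    hi <- inlet_outlet_pressures(tb + 1e-9 + 1, sp)
    expect_lt(abs(diff(lo[1, ] - hi[1, ])), 1e-5)
  }
  # hydrostatic start-up ramp
  expect_equal(unname(inlet_outlet_pressures(0, sp)[1, "p_out"]), 0)
  expect_equal(unname(inlet_outlet_pressures(sp$P0_ramp, sp)[1, "p_out"]), 4)
  expect_error(inlet_outlet_pressures(-1, sp), "non-negative")
})

test_that("disease scenarios rescale the leaflet stiffness tenfold", {
  base <- default_materials()
  expect_identical(scenario_params(base, "normal"), base)
  fib <- scenario_params(base, "fibrotic")
  expect_equal(fib$leaflet$c0, 40)
  expect_equal(fib$leaflet$c1, 1700.6)
  expect_identical(fib$wall, base$wall)
  atr <- scenario_params(base, "atrophic")
  expect_equal(atr$leaflet$c0, 0.4)
  expect_equal(atr$leaflet$c1, 17.006)
  expect_error(scenario_params(base, "calcified"))
  # hypertension leaves tissue alone but raises the offset above 30 mmHg
  cfg <- preset_config("coarse16", scenario = "hypertension")
  cfgn <- preset_config("coarse16")
  expect_identical(cfg$materials, cfgn$materials)
  expect_gt(cfg$profile$P0, 30)
})

test_that("the reference configuration carries the printed defaults", {
  cfg <- preset_config("reference")
  expect_identical(cfg$grid_n, c(50L, 50L, 150L))
  expect_equal(cfg$box, c(1, 1, 3))
  expect_equal(cfg$dt, 1e-5)
  expect_identical(cfg$cycles, 3L)
  expect_equal(cfg$rho, 1.08)
  expect_equal(cfg$mu, 0.36)
  expect_equal(cfg$profile$A, 0.5)
  expect_equal(cfg$profile$P0, 4)
  expect_equal(cfg$profile$T, 1)
  expect_equal(cfg$materials$wall$c2, 2.00)
  expect_equal(cfg$materials$wall$c3, 187.5)
  expect_equal(cfg$materials$sinus$c2, 0.50)
  expect_equal(cfg$materials$sinus$c3, 46.875)
  expect_equal(cfg$materials$leaflet$c0, 4)
  expect_equal(cfg$materials$leaflet$c1, 170.06)
  expect_equal(cfg$materials$wall$beta, 500)
  # the vein is truncated to the 3 cm fluid box
  expect_equal(cfg$geometry$l, 3)
})

test_that("a single driven step produces forward axial flow", {
  cfg <- preset_config("coarse16")
  cfg$profile <- pressure_profile(amplitude = 0.5, P0 = 0, eps = 0)
  st <- suppressMessages(init_simulation(cfg))
  st$t <- 0.1                       # on the rising sine
  st <- suppressWarnings(step_fsi(st, cfg))
  k <- round(0.5 / st$fluid$grid$h)
  expect_gt(sum(st$fluid$w[, , k]), 0)
})

test_that("restarting from a checkpoint continues identically", {
  cfg <- preset_config("coarse16")
  cfg$profile <- pressure_profile(amplitude = 0.5, P0 = 0, eps = 0)
  st <- suppressMessages(init_simulation(cfg))
  for (i in 1:10) st <- suppressWarnings(step_fsi(st, cfg))
  ck <- tempfile(fileext = ".rds")
  saveRDS(st, ck)
  for (i in 1:5) st <- suppressWarnings(step_fsi(st, cfg))
  st2 <- readRDS(ck)
  for (i in 1:5) st2 <- suppressWarnings(step_fsi(st2, cfg))
  expect_identical(st2$t, st$t)
  expect_equal(st2$x, st$x, tolerance = 1e-14)
  expect_equal(st2$fluid$w, st$fluid$w, tolerance = 1e-14)
})

test_that("an advected closed surface conserves its volume", {
  # a triangulated sphere advected through a frozen divergence-free field
  # for 1000 steps loses < 0.5% of its enclosed volume
  g <- fluid_grid(c(16, 16, 16), c(1, 1, 1), periodic = TRUE)
  s <- fluid_state(g)
  set.seed(77)
  s$u <- array(rnorm(16^3), c(16, 16, 16))
  s$v <- array(rnorm(16^3), c(16, 16, 16))
  s$w <- array(rnorm(16^3), c(16, 16, 16))
  s <- project(s, dt = 1)
  sc <- 2 / max(abs(c(s$u, s$v, s$w)))
  s$u <- s$u * sc; s$v <- s$v * sc; s$w <- s$w * sc
  # lat-long sphere triangulation
  nth <- 16; nph <- 32
  th <- seq(0, pi, length.out = nth + 1)
  ph <- seq(0, 2 * pi, length.out = nph + 1)[-1]
  sph <- function(m)
    cbind(sin(m[, 2]) * cos(m[, 1]), sin(m[, 2]) * sin(m[, 1]), cos(m[, 2]))
  pts <- rbind(c(0, 0, 1), sph(as.matrix(expand.grid(ph = ph, th = th[2:nth]))),
               c(0, 0, -1))
  idx <- function(i, j) 1 + (i - 1) * nph + ((j - 1) %% nph) + 1
  tris <- list()
  for (j in 1:nph) {
    tris[[length(tris) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
    tris[[length(tris) + 1]] <- c(nrow(pts), idx(nth - 1, j + 1), idx(nth - 1, j))
  }
  for (i in 1:(nth - 2)) for (j in 1:nph) {
    tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    tris[[length(tris) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  tris <- do.call(rbind, tris)
  vol <- function(x) {
    a <- x[tris[, 1], ]; b <- x[tris[, 2], ]; c3 <- x[tris[, 3], ]
    sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
        a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
        a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
  }
  x <- 0.5 + 0.2 * pts
  v0 <- abs(vol(x))
  dt <- 5e-4
  for (k in 1:1000) {
    u1 <- ib_interpolate(s, x)
    xm <- x + dt / 2 * u1
    xm <- (xm %% 1)
    u2 <- ib_interpolate(s, xm)
    x <- x + dt * u2
  }
  expect_lt(abs(abs(vol(x)) - v0) / v0, 0.005)
})
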