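test_that("strain energies match direct evaluation and vanish at identity", {
  poly <- material_params("polynomial", c0 = 4, c1 = 170.06)
  expo <- material_params("exponential", c2 = 2.00, c3 = 187.5)
  expect_identical(strain_energy(poly, diag(3)), 0)
  expect_identical(strain_energy(expo, diag(3)), 0)
  # simple shear gamma = 0.1 is isochoric: I1 - 3 = gamma^2, I3 = 1
  F <- simple_shear(0.1)
  expect_equal(strain_energy(poly, F), 4 * 0.01 + 170.06 * 1e-4,
               tolerance = 1e-12)
  expect_equal(strain_energy(expo, F), 2 * (exp(187.5 * 1e-4) - 1),
               tolerance = 1e-12)
})

test_that("PK1 stress is exactly zero at identity for all tissue sets", {
  for (mat in default_materials()) {
    P <- pk1_stress(mat, diag(3))
    expect_identical(max(abs(P)), 0)
  }
})

test_that("PK1 stress vanishes at pure rotations", {
  set.seed(11)
  for (mat in default_materials()) {
    for (k in 1:20) {
      R <- random_rotation()
      expect_lt(max(abs(pk1_stress(mat, R))), 1e-11)
    }
  }
})

test_that("PK1 shear component matches the closed form", {
  poly <- material_params("polynomial", c0 = 4, c1 = 170.06)
  g <- 0.1
  P <- pk1_stress(poly, simple_shear(g))
  # (F^{-T})_{12} = 0, so P12 = (2 c0 + 4 c1 gamma^2) gamma
  expect_equal(P[1, 2], (2 * 4 + 4 * 170.06 * g^2) * g, tolerance = 1e-12)
})

test_that("variational part of PK1 matches finite differences of the energy", {
  set.seed(7)
  h <- 1e-6
  for (mat in default_materials()) {
    worst <- 0
    for (k in 1:100) {
      F <- random_admissible_F()
      P <- pk1_stress(mat, F, corrected = FALSE)
      Pfd <- matrix(0, 3, 3)
      for (a in 1:3) for (b in 1:3) {
        Fp <- F; Fp[a, b] <- Fp[a, b] + h
        Fm <- F; Fm[a, b] <- Fm[a, b] - h
        Pfd[a, b] <- (strain_energy(mat, Fp) - strain_energy(mat, Fm)) /
          (2 * h)
      }
      worst <- max(worst, norm(P - Pfd, "F") / max(norm(Pfd, "F"), 1e-8))
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("Cauchy stress push-forward is symmetric and handles diagonals", {
  expect_equal(cauchy_stress(diag(c(2, 1, 1)), diag(c(3, 0, 0))),
               diag(c(3, 0, 0)))
  expect_identical(cauchy_stress(random_admissible_F(), matrix(0, 3, 3)),
                   matrix(0, 3, 3))
  set.seed(5)
  poly <- material_params("polynomial", c0 = 4, c1 = 170.06)
  for (k in 1:10) {
    F <- random_admissible_F()
    sig <- cauchy_stress(F, pk1_stress(poly, F))
    expect_lt(norm(sig - t(sig), "F") / max(norm(sig, "F"), 1e-12), 1e-10)
  }
})

test_that("Tresca maximum shear stress follows the principal stresses", {
  expect_equal(tresca_max_shear(diag(c(10, 5, 2))), 4)
  expect_equal(tresca_max_shear(matrix(0, 3, 3)), 0)
  # pure shear s on a plane: eigenvalues +s, 0, -s
  s <- 2.5
  sig <- matrix(0, 3, 3); sig[1, 2] <- sig[2, 1] <- s
  expect_equal(tresca_max_shear(sig), s, tolerance = 1e-12)
})

test_that("maximum principal Green-Lagrange strain matches closed forms", {
  expect_equal(max_principal_strain(diag(3)), 0)
  expect_equal(max_principal_strain(diag(c(1.2, 1, 1))), 0.22)
  # simple shear: E has 2x2 block [[0, g/2], [g/2, g^2/2]]
  g <- 0.3
  lam <- g^2 / 4 + sqrt((g^2 / 4)^2 + g^2 / 4)
  expect_equal(max_principal_strain(simple_shear(g)), lam, tolerance = 1e-12)
})

test_that("volumetric penalty grows monotonically with |log J|", {
  mat <- material_params("polynomial", c0 = 0, c1 = 0, beta = 500)
  lams <- c(0.8, 0.9, 0.95, 1.05, 1.1, 1.25)
  en <- vapply(lams, function(l) strain_energy(mat, diag(rep(l, 3))),
               numeric(1))
  o <- order(abs(log(lams^3)))
  expect_true(all(diff(en[o]) > 0))
})

test_that("scaling the stress-like coefficients scales the elastic stress", {
  set.seed(3)
  F <- random_admissible_F()
  k <- 10
  m1 <- material_params("polynomial", c0 = 4, c1 = 170.06, beta = 500)
  mk <- material_params("polynomial", c0 = 4 * k, c1 = 170.06 * k,
                        beta = 500)
  vol <- function(m, F) {
    d <- deformation_state(F)
    m$beta * log(d$I3) * t(solve(F))
  }
  el1 <- pk1_stress(m1, F) - vol(m1, F)
  elk <- pk1_stress(mk, F) - vol(mk, F)
  expect_equal(elk, k * el1, tolerance = 1e-12)
})

test_that("invalid parameters and inverted deformations are rejected", {
  expect_error(material_params("polynomial", c0 = 4), "c1")
  expect_error(material_params("exponential", c2 = 1, c3 = 2, c0 = 1),
               "must not set")
  expect_error(material_params("polynomial", c0 = 4, c1 = 1, beta = -1),
               "beta")
  expect_error(deformation_state(diag(c(-1, 1, 1))), "inverted")
})
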