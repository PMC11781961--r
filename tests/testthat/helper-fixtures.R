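# shared fixtures: deterministic random deformations and rotations

simple_shear <- function(gamma) {
  F <- diag(3); F[1, 2] <- gamma
  F
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to det +1
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_admissible_F <- function(spread = 0.15) {
  repeat {
    F <- diag(3) + matrix(runif(9, -spread, spread), 3, 3)
    if (det(F) > 0.2) return(F)
  }
}

# analytic Poiseuille axial velocity on a circle of radius R
poiseuille_profile <- function(r, R, dpdz, mu) {
  dpdz / (4 * mu) * (R^2 - r^2)
}

# unit regular-ish tetrahedron
unit_tet <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}
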