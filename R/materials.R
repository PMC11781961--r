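#' Hyperelastic material parameter set
#'
#' Constructs the constitutive parameters of one tissue region.  Two
#' incompressible isotropic strain-energy forms are supported, both augmented
#' with a logarithmic volumetric penalty \eqn{\frac{\beta}{4}\log^2 I_3}:
#'
#' \describe{
#'   \item{polynomial}{\eqn{\Psi = c_0 (I_1 - 3) + c_1 (I_1 - 3)^2 +
#'     \frac{\beta}{4}\log^2 I_3} (used for the valve leaflets).}
#'   \item{exponential}{\eqn{\Psi = c_2 \{\exp[c_3 (I_1 - 3)^2] - 1\} +
#'     \frac{\beta}{4}\log^2 I_3} (used for the vein wall and sinus).}
#' }
#'
#' Here \eqn{I_1 = \mathrm{tr}(F^T F)} and \eqn{I_3 = \det(F^T F)} are
#' invariants of the deformation gradient \eqn{F}.  Stress-like coefficients
#' (`c0`, `c2`, `beta`) are in kPa; `c1` and `c3` are dimensionless
#' multipliers of powers of the dimensionless quantity \eqn{I_1 - 3}.
#'
#' @param model_form `"polynomial"` or `"exponential"`.
#' @param c0,c1 polynomial coefficients (kPa, dimensionless); required for
#'   `model_form = "polynomial"`.
#' @param c2,c3 exponential coefficients (kPa, dimensionless); required for
#'   `model_form = "exponential"`.
#' @param beta volumetric penalty modulus (kPa), strictly positive.
#' @return An object of class `material_params`.
#' @examples
#' leaflet <- material_params("polynomial", c0 = 4, c1 = 170.06)
#' wall    <- material_params("exponential", c2 = 2.00, c3 = 187.5)
#' @export
material_params <- function(model_form = c("polynomial", "exponential"),
                            c0 = NULL, c1 = NULL, c2 = NULL, c3 = NULL,
                            beta = 500) {
  model_form <- match.arg(model_form)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a single positive number (kPa)")
  if (model_form == "polynomial") {
    if (is.null(c0) || is.null(c1))
      stop("polynomial form requires 'c0' and 'c1'")
    if (!is.null(c2) || !is.null(c3))
      stop("polynomial form must not set 'c2'/'c3'")
    if (c0 < 0 || c1 < 0) stop("coefficients must be non-negative")
    out <- list(model_form = model_form, c0 = c0, c1 = c1, beta = beta)
  } else {
    if (is.null(c2) || is.null(c3))
      stop("exponential form requires 'c2' and 'c3'")
    if (!is.null(c0) || !is.null(c1))
      stop("exponential form must not set 'c0'/'c1'")
    if (c2 < 0 || c3 < 0) stop("coefficients must be non-negative")
    out <- list(model_form = model_form, c2 = c2, c3 = c3, beta = beta)
  }
  class(out) <- "material_params"
  out
}

#' @export
print.material_params <- function(x, ...) {
  cat("<material_params>", x$model_form, "\n")
  if (x$model_form == "polynomial")
    cat("  c0 =", x$c0, "kPa, c1 =", x$c1, "\n")
  else
    cat("  c2 =", x$c2, "kPa, c3 =", x$c3, "\n")
  cat("  beta =", x$beta, "kPa\n")
  invisible(x)
}

#' Default per-region tissue parameters
#'
#' The reference parameter table: leaflets follow the polynomial form,
#' wall and sinus the exponential form with different stiffnesses.  The
#' volumetric penalty is shared (`beta`, default 500 kPa).
#'
#' @param beta volumetric penalty (kPa) applied to every region.
#' @return Named list with elements `wall`, `sinus`, `leaflet`.
#' @export
default_materials <- function(beta = 500) {
  list(
    wall    = material_params("exponential", c2 = 2.00, c3 = 187.5,  beta = beta),
    sinus   = material_params("exponential", c2 = 0.50, c3 = 46.875, beta = beta),
    leaflet = material_params("polynomial",  c0 = 4,    c1 = 170.06, beta = beta)
  )
}

#' Deformation state derived from a deformation gradient
#'
#' @param F 3x3 deformation gradient (dimensionless).
#' @return List with `F`, invariants `I1`, `I3` and `J = det F`.
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L)) || !all(is.finite(F)))
    stop("F must be a finite 3x3 matrix")
  J <- det(F)
  if (J <= 0) stop("inverted deformation: det F = ", signif(J, 4), " <= 0")
  structure(list(F = F, I1 = sum(F * F), I3 = J^2, J = J),
            class = "deformation_state")
}

as_deformation <- function(def) {
  if (inherits(def, "deformation_state")) def else deformation_state(def)
}

#' Strain-energy density
#'
#' Evaluates the strain-energy density \eqn{\Psi(F)} of a material in kPa.
#' \eqn{\Psi(I) = 0} for both model forms.
#'
#' @param mat a [material_params] object.
#' @param def a [deformation_state] or a 3x3 deformation gradient.
#' @return Energy density in kPa (per unit reference volume).
#' @export
strain_energy <- function(mat, def) {
  def <- as_deformation(def)
  q <- def$I1 - 3
  vol <- mat$beta / 4 * log(def$I3)^2
  if (mat$model_form == "polynomial")
    mat$c0 * q + mat$c1 * q^2 + vol
  else
    mat$c2 * (exp(mat$c3 * q^2) - 1) + vol
}

#' First Piola--Kirchhoff stress
#'
#' Evaluates the modified first Piola--Kirchhoff stress tensor (kPa).  On top
#' of the variational stress \eqn{\partial\Psi/\partial F}, correction terms
#' proportional to \eqn{F^{-T}} are subtracted so that \eqn{P(I) = 0}
#' exactly; these act as a reference pressure that suppresses spurious volume
#' loss across the fluid--structure interface:
#' \deqn{P_{poly} = [2c_0 + 4c_1(I_1-3)] F - [2c_0 + 4c_1(I_1-3)] F^{-T}
#'   + \beta \log(I_3) F^{-T},}
#' \deqn{P_{exp} = 4c_2c_3(I_1-3)e^{c_3(I_1-3)^2} (F - F^{-T})
#'   + \beta \log(I_3) F^{-T}.}
#'
#' @inheritParams strain_energy
#' @param corrected logical; if `FALSE`, return the plain variational stress
#'   \eqn{\partial\Psi/\partial F} without the correction terms.
#' @return 3x3 stress tensor in kPa.
#' @export
pk1_stress <- function(mat, def, corrected = TRUE) {
  def <- as_deformation(def)
  F <- def$F
  q <- def$I1 - 3
  Finvt <- t(solve(F))
  a <- if (mat$model_form == "polynomial")
    2 * mat$c0 + 4 * mat$c1 * q
  else
    4 * mat$c2 * mat$c3 * q * exp(mat$c3 * q^2)
  P <- a * F + mat$beta * log(def$I3) * Finvt
  if (corrected) P <- P - a * Finvt
  P
}

#' Cauchy stress from a first Piola--Kirchhoff stress
#'
#' \eqn{\sigma = J^{-1} P F^T}.  For the isotropic energies used here
#' (including the \eqn{F^{-T}} correction terms, which push forward to a
#' pressure) the result is symmetric.
#'
#' @param def a [deformation_state] or 3x3 deformation gradient.
#' @param P 3x3 first Piola--Kirchhoff stress (kPa).
#' @return 3x3 Cauchy stress (kPa).
#' @export
cauchy_stress <- function(def, P) {
  def <- as_deformation(def)
  (P %*% t(def$F)) / def$J
}

#' Tresca maximum shear stress
#'
#' Half the spread of the principal stresses,
#' \eqn{\tau_{max} = (\sigma_1 - \sigma_3)/2}, a standard damage indicator.
#' The input is symmetrised before the eigendecomposition.
#'
#' @param sigma 3x3 (near-)symmetric Cauchy stress (kPa).
#' @return Non-negative scalar (kPa).
#' @export
tresca_max_shear <- function(sigma) {
  s <- (sigma + t(sigma)) / 2
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  (max(ev) - min(ev)) / 2
}

#' Maximum principal Green--Lagrange strain
#'
#' Largest eigenvalue of \eqn{E = (F^T F - I)/2}.
#'
#' @inheritParams strain_energy
#' @return Dimensionless scalar.
#' @export
max_principal_strain <- function(def) {
  def <- as_deformation(def)
  C <- crossprod(def$F)
  E <- (C - diag(3)) / 2
  max(eigen(E, symmetric = TRUE, only.values = TRUE)$values)
}

## ---- vectorised internals used by the FE assembly -------------------------
## Tensors stored as n x 9 matrices, column-major within each row
## (F11,F21,F31,F12,F22,F32,F13,F23,F33).

# batched determinant of n x 9 tensor rows
det3_batch <- function(F) {
  F[, 1] * (F[, 5] * F[, 9] - F[, 8] * F[, 6]) -
  F[, 4] * (F[, 2] * F[, 9] - F[, 8] * F[, 3]) +
  F[, 7] * (F[, 2] * F[, 6] - F[, 5] * F[, 3])
}

# batched inverse-transpose: rows of cofactor matrix / det
invt3_batch <- function(F, detF = det3_batch(F)) {
  ## cofactor C_ij = d det / d F_ij; F^{-T} = C / det
  C <- matrix(0, nrow(F), 9)
  C[, 1] <- F[, 5] * F[, 9] - F[, 8] * F[, 6]
  C[, 2] <- F[, 7] * F[, 6] - F[, 4] * F[, 9]
  C[, 3] <- F[, 4] * F[, 8] - F[, 7] * F[, 5]
  C[, 4] <- F[, 8] * F[, 3] - F[, 2] * F[, 9]
  C[, 5] <- F[, 1] * F[, 9] - F[, 7] * F[, 3]
  C[, 6] <- F[, 7] * F[, 2] - F[, 1] * F[, 8]
  C[, 7] <- F[, 2] * F[, 6] - F[, 5] * F[, 3]
  C[, 8] <- F[, 4] * F[, 3] - F[, 1] * F[, 6]
  C[, 9] <- F[, 1] * F[, 5] - F[, 4] * F[, 2]
  C / detF
}

# batched corrected PK1 (kPa) for rows of F under a single material
pk1_batch <- function(mat, F) {
  detF <- det3_batch(F)
  if (any(detF <= 0))
    stop("inverted deformation in ", sum(detF <= 0), " element(s)")
  q <- rowSums(F * F) - 3
  Finvt <- invt3_batch(F, detF)
  a <- if (mat$model_form == "polynomial")
    2 * mat$c0 + 4 * mat$c1 * q
  else
    4 * mat$c2 * mat$c3 * q * exp(mat$c3 * q^2)
  logI3 <- 2 * log(detF)
  a * F + (mat$beta * logI3 - a) * Finvt
}
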