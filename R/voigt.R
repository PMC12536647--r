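#' Voigt-notation tensor utilities
#'
#' The package fixes the Voigt ordering to (11, 22, 33, 23, 13, 12) with
#' engineering shear strains (gamma = 2*eps) in the strain vector. All
#' constitutive matrices are transcribed and rotated in this convention.
#'
#' @name voigt
NULL

# Voigt index pairs in the package ordering.
.voigt_pairs <- matrix(c(1, 1, 2, 2, 3, 3, 2, 3, 1, 3, 1, 2),
                       ncol = 2, byrow = TRUE)

#' Bond stress-transformation matrix of a rotation
#'
#' Returns the 6x6 matrix `M` such that Voigt stress transforms as
#' `sigma' = M sigma` under the rotation `R` (with x' = R x). Stiffness then
#' transforms as `c' = M c t(M)` and the stress-charge coupling matrix as
#' `e' = R e t(M)`.
#'
#' @param R 3x3 orthonormal rotation matrix.
#' @return 6x6 Bond matrix.
#' @export
bond_stress_matrix <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  M <- matrix(0, 6, 6)
  for (I in 1:6) {
    i <- .voigt_pairs[I, 1]; j <- .voigt_pairs[I, 2]
    for (J in 1:6) {
      k <- .voigt_pairs[J, 1]; l <- .voigt_pairs[J, 2]
      M[I, J] <- R[i, k] * R[j, l] + if (k != l) R[i, l] * R[j, k] else 0
    }
  }
  M
}

#' Symmetric 3x3 tensor to Voigt vector
#'
#' @param S symmetric 3x3 matrix.
#' @param engineering logical; double the shear components (strain convention).
#' @return length-6 vector in ordering (11,22,33,23,13,12).
#' @export
tensor_to_voigt <- function(S, engineering = FALSE) {
  v <- c(S[1, 1], S[2, 2], S[3, 3], S[2, 3], S[1, 3], S[1, 2])
  if (engineering) v[4:6] <- 2 * v[4:6]
  v
}

#' Voigt vector to symmetric 3x3 tensor
#'
#' @param v length-6 Voigt vector.
#' @param engineering logical; halve the shear components (strain convention).
#' @return symmetric 3x3 matrix.
#' @export
voigt_to_tensor <- function(v, engineering = FALSE) {
  s <- if (engineering) v[4:6] / 2 else v[4:6]
  matrix(c(v[1], s[3], s[2],
           s[3], v[2], s[1],
           s[2], s[1], v[3]), 3, 3)
}

#' Isotropic elasticity matrix
#'
#' 6x6 stiffness in Voigt notation from Young's modulus and Poisson ratio.
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio.
#' @return 6x6 matrix, Pa.
#' @export
iso_elasticity <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

#' von Mises equivalent stress
#'
#' `sqrt(3/2 * dev(sigma) : dev(sigma))` for a symmetric stress tensor. 2x2
#' plane-strain input is promoted to 3D with `sigma_zz = nu*(s_xx + s_yy)`;
#' a length-6 Voigt vector is also accepted.
#'
#' @param stress symmetric 3x3 matrix, 2x2 matrix, or Voigt 6-vector.
#' @param nu Poisson ratio used only for the 2x2 plane-strain promotion.
#' @return scalar, Pa.
#' @export
von_mises <- function(stress, nu = 0.3) {
  if (is.matrix(stress)) {
    if (max(abs(stress - t(stress))) > 1e-8 * max(1, max(abs(stress)))) {
      stop("von_mises: stress tensor must be symmetric")
    }
    if (all(dim(stress) == c(2, 2))) {
      S <- matrix(0, 3, 3)
      S[1:2, 1:2] <- stress
      S[3, 3] <- nu * (stress[1, 1] + stress[2, 2])
      stress <- S
    }
    v <- tensor_to_voigt(stress)
  } else {
    stopifnot(length(stress) == 6)
    v <- stress
  }
  s11 <- v[1]; s22 <- v[2]; s33 <- v[3]
  sqrt(0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) +
         3 * (v[4]^2 + v[5]^2 + v[6]^2))
}

# von Mises for element-wise Voigt stress stored as an n x 6 matrix.
von_mises_rows <- function(sv) {
  sqrt(0.5 * ((sv[, 1] - sv[, 2])^2 + (sv[, 2] - sv[, 3])^2 +
                (sv[, 3] - sv[, 1])^2) +
         3 * (sv[, 4]^2 + sv[, 5]^2 + sv[, 6]^2))
}
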