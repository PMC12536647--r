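# Brute-force tensor rotation oracles, independent of the Bond-matrix path.

voigt_pairs <- matrix(c(1, 1, 2, 2, 3, 3, 2, 3, 1, 3, 1, 2),
                      ncol = 2, byrow = TRUE)

# 6x6 Voigt stiffness -> full 3x3x3x3 tensor
voigt_to_tensor4 <- function(C) {
  A <- array(0, c(3, 3, 3, 3))
  for (I in 1:6) for (J in 1:6) {
    i <- voigt_pairs[I, 1]; j <- voigt_pairs[I, 2]
    k <- voigt_pairs[J, 1]; l <- voigt_pairs[J, 2]
    for (ii in unique(list(c(i, j), c(j, i)))) {
      for (kk in unique(list(c(k, l), c(l, k)))) {
        A[ii[1], ii[2], kk[1], kk[2]] <- C[I, J]
      }
    }
  }
  A
}

tensor4_to_voigt <- function(A) {
  C <- matrix(0, 6, 6)
  for (I in 1:6) for (J in 1:6) {
    C[I, J] <- A[voigt_pairs[I, 1], voigt_pairs[I, 2],
                 voigt_pairs[J, 1], voigt_pairs[J, 2]]
  }
  C
}

rotate_tensor4 <- function(A, R) {
  B <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3) for (t in 1:3) {
      s <- s + R[i, p] * R[j, q] * R[k, r] * R[l, t] * A[p, q, r, t]
    }
    B[i, j, k, l] <- s
  }
  B
}

# 3x6 stress-charge e-matrix -> full 3x3x3 tensor and back
e_to_tensor3 <- function(e) {
  A <- array(0, c(3, 3, 3))
  for (i in 1:3) for (J in 1:6) {
    k <- voigt_pairs[J, 1]; l <- voigt_pairs[J, 2]
    A[i, k, l] <- e[i, J]; A[i, l, k] <- e[i, J]
  }
  A
}

tensor3_to_e <- function(A) {
  e <- matrix(0, 3, 6)
  for (i in 1:3) for (J in 1:6) {
    e[i, J] <- A[i, voigt_pairs[J, 1], voigt_pairs[J, 2]]
  }
  e
}

rotate_tensor3 <- function(A, R) {
  B <- array(0, c(3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    s <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3) {
      s <- s + R[i, p] * R[j, q] * R[k, r] * A[p, q, r]
    }
    B[i, j, k] <- s
  }
  B
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# analytic 2D disc-dipole exterior field: V = V0 a cos(theta)/r (theta from
# the +y axis); returns the field vector at points relative to the centre
disc_dipole_E <- function(pts, center, a, V0) {
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  r2 <- dx^2 + dy^2
  p <- V0 * a
  # E = -grad V with V = p * y / r^2
  Ex <- p * 2 * dx * dy / r2^2
  Ey <- p * (2 * dy^2 / r2^2 - 1 / r2)
  cbind(Ex, Ey)
}
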