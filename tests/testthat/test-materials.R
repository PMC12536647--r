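test_that("registry returns validated records with the expected structure", {
  for (nm in c("CFO", "BTO", "HAP", "alginate", "cell")) {
    m <- get_material(nm)
    expect_s3_class(m, "material_props")
    ev <- eigen(m$elasticity_cE, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(dim(m$piezo_e), c(3, 6))
    expect_true(all(diag(m$permittivity_rs) >= 1))
    expect_gte(m$conductivity, 0)
  }
  # hydrogel, core and cell are not piezoelectric
  expect_equal(get_material("alginate")$piezo_e, matrix(0, 3, 6))
  expect_equal(get_material("cell")$piezo_e, matrix(0, 3, 6))
  expect_equal(get_material("CFO")$piezo_e, matrix(0, 3, 6))
  # only the core is magnetostrictive
  for (nm in c("BTO", "HAP", "alginate", "cell")) {
    expect_identical(get_material(nm)$lambda_s, 0)
    expect_identical(get_material(nm)$Ms, 0)
  }
  expect_error(get_material("bone"), "valid names")
})

test_that("hydroxyapatite c-axis coupling dominates the transverse one", {
  e <- get_material("HAP")$piezo_e
  expect_gt(abs(e[3, 3]), abs(e[3, 1]))
})

test_that("material rotation follows the tensor transformation rules", {
  hap <- get_material("HAP")
  # identity leaves every tensor bitwise equal
  id <- rotate_material(hap, diag(3))
  expect_identical(id$elasticity_cE, hap$elasticity_cE)
  expect_identical(id$piezo_e, hap$piezo_e)
  # group property: two successive 90 deg rotations = one 180 deg rotation
  r90 <- rotation_about("z", 90); r180 <- rotation_about("z", 180)
  twice <- rotate_material(rotate_material(hap, r90), r90)
  once <- rotate_material(hap, r180)
  expect_lt(max(abs(twice$elasticity_cE - once$elasticity_cE)), 1e-9 * 1e11)
  expect_lt(max(abs(twice$piezo_e - once$piezo_e)), 1e-9)
  # brute-force 4th/3rd/2nd-rank oracle on a random rotation
  R <- random_rotation(42)
  got <- rotate_material(hap, R)
  C4 <- rotate_tensor4(voigt_to_tensor4(hap$elasticity_cE), R)
  expect_equal(got$elasticity_cE, tensor4_to_voigt(C4),
               tolerance = 1e-10)
  E3 <- rotate_tensor3(e_to_tensor3(hap$piezo_e), R)
  expect_equal(got$piezo_e, tensor3_to_e(E3), tolerance = 1e-10)
  expect_equal(got$permittivity_rs, R %*% hap$permittivity_rs %*% t(R),
               tolerance = 1e-12)
  expect_error(rotate_material(hap, matrix(1, 3, 3)), "orthonormal")
})

test_that("rotated response equals back-rotated response to a rotated field", {
  hap <- get_material("HAP")
  Ry <- rotation_about("y", 90)   # maps +z onto +x
  rot <- rotate_material(hap, Ry)
  set.seed(7)
  for (rep in 1:5) {
    eps <- rnorm(6, sd = 1e-6)
    # strain must co-rotate as a tensor for the comparison
    S <- voigt_to_tensor(eps, engineering = TRUE)
    Sr <- Ry %*% S %*% t(Ry)
    eps_r <- tensor_to_voigt(Sr, engineering = TRUE)
    Ez <- c(0, 0, rnorm(1, sd = 1e3))
    sig_rot <- rot$elasticity_cE %*% eps_r - t(rot$piezo_e) %*% (Ry %*% Ez)
    sig_ref <- hap$elasticity_cE %*% eps - t(hap$piezo_e) %*% Ez
    Sig_ref <- voigt_to_tensor(as.numeric(sig_ref))
    expect_equal(as.numeric(sig_rot),
                 tensor_to_voigt(Ry %*% Sig_ref %*% t(Ry)),
                 tolerance = 1e-8)
  }
})

test_that("Bond rotation preserves elastic invariants and stability holds", {
  for (nm in c("CFO", "BTO", "HAP")) {
    m <- get_material(nm)
    R <- random_rotation(match(nm, c("CFO", "BTO", "HAP")))
    rot <- rotate_material(m, R)
    # elastic invariants live in the tensorial (Mandel) representation,
    # where the rotation acts orthogonally
    S <- diag(c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2)))
    mandel <- function(C) S %*% C %*% S
    expect_equal(sort(eigen(mandel(rot$elasticity_cE), only.values = TRUE)$values),
                 sort(eigen(mandel(m$elasticity_cE), only.values = TRUE)$values),
                 tolerance = 1e-9)
    # non-negative stored energy for random small (strain, field) pairs
    set.seed(11)
    for (rep in 1:20) {
      eps <- rnorm(6, sd = 1e-5); E <- rnorm(3, sd = 1e4)
      sig <- m$elasticity_cE %*% eps - t(m$piezo_e) %*% E
      D <- m$piezo_e %*% eps + eps0 * m$permittivity_rs %*% E
      U <- 0.5 * (sum(sig * eps) + sum(D * E))
      expect_gte(U, 0)
    }
  }
})

test_that("von Mises closed forms hold and asymmetry is rejected", {
  s <- 3.7e5
  expect_equal(von_mises(diag(c(s, 0, 0))), s)
  expect_equal(von_mises(diag(c(s, s, s))), 0)
  tau <- 2.2e4
  sh <- matrix(0, 3, 3); sh[1, 2] <- sh[2, 1] <- tau
  expect_equal(von_mises(sh), sqrt(3) * tau)
  # plane tensor promoted with sigma_zz = nu (sxx + syy)
  p2 <- diag(c(s, s))
  expect_equal(von_mises(p2, nu = 0.5), 0)
  bad <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(von_mises(bad), "symmetric")
})
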