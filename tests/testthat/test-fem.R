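alg <- function() get_material("alginate")

test_that("conduction solver reproduces the parallel-plate ramp", {
  msh <- rect_grid_mesh(c(0, 1e-6), c(0, 1e-6), 6, 6)
  sol <- solve_conduction(msh, list(gel = alg()), list(bottom = 0, top = 1))
  expect_equal(unname(sol$E_mag), rep(1 / 1e-6, nrow(msh$elem)),
               tolerance = 1e-10)
  expect_error(solve_conduction(msh, list(gel = alg()), list()), "Dirichlet")
})

test_that("dielectric sphere in a uniform field matches the closed form", {
  # permittivity contrast enters a conduction-type solve identically, so the
  # sigma-Laplace path is exercised with the permittivity ratio as contrast
  a <- 70e-9
  msh <- make_axisym_particle_mesh(a, "sphere", box_r = 1e-6, box_z = 1e-6,
                                   h = 8e-9, medium_name = "medium")
  er <- 10
  mats <- list(sphere = list(conductivity = er), medium = list(conductivity = 1))
  E0 <- 1e3
  sol <- solve_conduction(msh, mats,
                          list(outer_top = -E0 * 1e-6, outer_bottom = E0 * 1e-6,
                               outer_side = function(n) -E0 * n[, 2]))
  inner <- msh$subdomain == "sphere"
  w <- abs(tri_areas(msh))[inner] * elem_centroids(msh)[inner, 1]
  Ein <- sum(sol$E_mag[inner] * w) / sum(w)
  expect_equal(Ein, 3 * E0 / (er + 2), tolerance = 0.05)
})

test_that("magnetizable sphere reproduces the demagnetization closed form", {
  a <- 70e-9
  msh <- make_axisym_particle_mesh(a, "sphere", box_r = 1e-6, box_z = 1e-6,
                                   h = 8e-9, medium_name = "gel")
  mur <- 100
  sol <- solve_magnetostatics(msh, list(sphere = list(mu_r = mur, Ms = 0),
                                        gel = list(mu_r = 1, Ms = 0)),
                              B_applied = 0.3)
  H0 <- 0.3 / mu0
  Hin <- sqrt(rowSums(sol$H[msh$subdomain == "sphere", ]^2))
  expect_equal(mean(Hin), 3 * H0 / (mur + 2), tolerance = 0.10)
  # vacuum limit: homogeneous mu_r = 1 gives the uniform background field
  sol1 <- solve_magnetostatics(msh, list(sphere = list(mu_r = 1, Ms = 0),
                                         gel = list(mu_r = 1, Ms = 0)),
                               B_applied = 0.3)
  expect_equal(unname(sol1$H[, 2]), rep(H0, nrow(msh$elem)), tolerance = 1e-8)
  expect_equal(max(abs(sol1$M)), 0)
})

test_that("dipole-surface far field decays as the point-dipole law", {
  # axisymmetric (3D) particle: |E| ~ r^-3 on the equatorial ray
  a <- 70e-9
  msh <- make_axisym_particle_mesh(a, "p", box_r = 4e-6, box_z = 4e-6,
                                   h = 10e-9, medium_name = "gel", hole = TRUE)
  V0 <- 1.36e-3
  ctr <- c(0, 0)
  sol <- solve_conduction(msh, list(gel = alg()), list(
    outer_top = 0, outer_bottom = 0, outer_side = 0,
    particle_surface_1 = function(n) dipole_surface_potential(n, ctr, c(0, 1), V0)
  ))
  # the potential matches the point-dipole closed form V0 a^2 cos(theta)/r^2
  Vtrue <- V0 * a^2 * msh$nodes[, 2] / pmax(rowSums(msh$nodes^2), a^2)^1.5
  expect_lt(max(abs(sol$V - Vtrue)) / V0, 0.02)
  # |E| r^3 (shape-corrected) is constant within 10% over a decade of r
  rs <- seq(0.2e-6, 2.0e-6, by = 0.2e-6)
  idx <- unique(locate_elements(msh, cbind(rs, 0)))
  cen <- elem_centroids(msh)[idx, , drop = FALSE]
  rc <- sqrt(rowSums(cen^2)); ct <- cen[, 2] / rc
  const <- sol$E_mag[idx] * rc^3 / sqrt(1 + 3 * ct^2)
  expect_lt(max(const) / min(const), 1.10)
})

test_that("planar disc dipoles superpose linearly far from the surfaces", {
  dip <- make_dipole_grid(spacing = 5e-6, V0 = 1.36e-3)  # 2x2 discs
  msh <- make_dipole_array_mesh(dip, delta = 0.25e-6, h = 20e-9)
  dirichlet <- list(outer_top = 0, outer_bottom = 0, outer_side = 0)
  for (i in 1:4) {
    local({
      ci <- dip$centers[i, ]
      dirichlet[[paste0("particle_surface_", i)]] <<-
        function(n) dipole_surface_potential(n, ci, c(0, 1), dip$V0)
    })
  }
  sol <- solve_conduction(msh, list(gel = alg()), dirichlet)
  # element-wise gradients carry sampling noise, so the comparison is made
  # on area-averaged |E| over annuli around two of the discs, against the
  # area-averaged analytic superposition on the same elements
  cen <- elem_centroids(msh)
  A <- tri_areas(msh)
  Ean <- 0
  for (i in 1:4) Ean <- Ean + disc_dipole_E(cen, dip$centers[i, ], dip$radius, dip$V0)
  Ean_mag <- sqrt(rowSums(Ean^2))
  for (i in c(1L, 4L)) {
    r <- sqrt(rowSums(sweep(cen, 2, dip$centers[i, ])^2))
    ring <- r > 0.15e-6 & r < 0.45e-6
    fem_avg <- sum(sol$E_mag[ring] * A[ring]) / sum(A[ring])
    an_avg <- sum(Ean_mag[ring] * A[ring]) / sum(A[ring])
    expect_lt(abs(fem_avg / an_avg - 1), 0.05)
  }
})

test_that("free piezoelectric bar actuates at d33 E", {
  bto <- get_material("BTO")
  L <- 400e-9; R <- 50e-9
  msh <- rect_grid_mesh(c(0, R), c(0, L), 5, 30, subdomain = "bar",
                        coord = "axisym")
  E0 <- 1e5
  sol <- solve_piezo(msh, list(bar = bto), electric_subdomains = "bar",
                     elec_dirichlet = list(bottom = 0, top = -E0 * L),
                     mech_roller = list(bottom = 2L))
  topn <- boundary_nodes(msh, "top"); botn <- boundary_nodes(msh, "bottom")
  eps_zz <- (mean(sol$u[topn, 2]) - mean(sol$u[botn, 2])) / L
  d <- bto$piezo_e %*% solve(bto$elasticity_cE)
  expect_equal(eps_zz, unname(d[3, 3] * E0), tolerance = 0.02)
})

test_that("null drive and zero coupling give identically zero response", {
  bto <- get_material("BTO")
  msh <- rect_grid_mesh(c(0, 1e-7), c(0, 4e-7), 4, 10, subdomain = "bar")
  sol <- solve_piezo(msh, list(bar = bto), electric_subdomains = "bar",
                     elec_dirichlet = list(bottom = 0, top = 0),
                     mech_roller = list(bottom = 2L, left = 1L))
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(max(sol$vonMises), 0)
})

test_that("assembled coupled system is symmetric", {
  msh <- rect_grid_mesh(c(0, 1e-7), c(0, 2e-7), 3, 6, subdomain = "bar")
  sys <- magnetopiezo:::assemble_piezo(msh, list(bar = get_material("BTO")),
                                       "bar")
  expect_lt(max(abs(sys$A - Matrix::t(sys$A))), 1e-6 * max(abs(sys$A)))
})

test_that("magnetostrictive strain follows the quadratic law", {
  expect_equal(magnetostrictive_strain(c(0, 0, 0), 1e5, -1e-4), rep(0, 6))
  Ms <- 5.5e4; ls <- -1.1e-4
  sat <- magnetostrictive_strain(c(0, 0, Ms), Ms, ls)
  expect_equal(sat[3], ls)
  expect_equal(sat[1], -ls / 2)
  expect_equal(sat[2], -ls / 2)
  set.seed(3)
  for (k in 1:10) {
    M <- rnorm(3, sd = 4e4)
    v <- magnetostrictive_strain(M, Ms, ls)
    expect_lt(abs(v[1] + v[2] + v[3]), 1e-12 * max(abs(v)))
  }
  expect_error(magnetostrictive_strain(c(0, 0, 1), 0, ls), "positive")
})

test_that("scalar solutions converge under mesh refinement", {
  a <- 70e-9; er <- 10; E0 <- 1e3
  err <- sapply(c(16e-9, 8e-9), function(h) {
    msh <- make_axisym_particle_mesh(a, "sphere", box_r = 1e-6, box_z = 1e-6,
                                     h = h, medium_name = "medium")
    mats <- list(sphere = list(conductivity = er),
                 medium = list(conductivity = 1))
    sol <- solve_conduction(msh, mats,
                            list(outer_top = -E0 * 1e-6,
                                 outer_bottom = E0 * 1e-6,
                                 outer_side = function(n) -E0 * n[, 2]))
    inner <- msh$subdomain == "sphere"
    w <- abs(tri_areas(msh))[inner] * elem_centroids(msh)[inner, 1]
    abs(sum(sol$E_mag[inner] * w) / sum(w) - 3 * E0 / (er + 2))
  })
  expect_lt(err[2], err[1])
})
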