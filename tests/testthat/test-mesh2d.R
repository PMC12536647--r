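test_that("axisymmetric particle mesh reproduces the geometry", {
  msh <- make_menp_axisym_mesh()
  expect_true(all(c("core", "shell", "gel") %in% msh$subdomain))
  mesh_audit(msh)
  A <- tri_areas(msh)
  # half-plane cross-section of the 1 um square domain
  expect_equal(sum(A), 0.5 * (1e-6)^2, tolerance = 0.005)
  # half-annulus shell cross-section
  expect_equal(sum(A[msh$subdomain == "shell"]),
               pi / 2 * ((70e-9)^2 - (45e-9)^2), tolerance = 0.01)
  expect_true(all(msh$nodes[, 1] >= 0))
  ax <- boundary_nodes(msh, "axis")
  expect_true(all(abs(msh$nodes[ax, 1]) == 0))
})

test_that("axisymmetric mesh preconditions are enforced", {
  expect_error(make_menp_axisym_mesh(h = 30e-9), "too coarse")
  expect_error(make_menp_axisym_mesh(gel_side = 100e-9), "exceed")
})

test_that("dipole grids have the expected counts and are reproducible", {
  expect_equal(nrow(make_dipole_grid(spacing = 1.0e-6)$centers), 100)
  expect_equal(nrow(make_dipole_grid(spacing = 1.40e-6)$centers), 49)
  expect_error(make_dipole_grid(spacing = 1e-7), "exceed")
  j1 <- make_dipole_grid(spacing = 1.4e-6, jitter = "random", seed = 5)
  j2 <- make_dipole_grid(spacing = 1.4e-6, jitter = "random", seed = 5)
  expect_identical(j1$centers, j2$centers)
  expect_gt(min(dist(j1$centers)), 2 * j1$radius)
  # jitter stays inside the nominal cells
  expect_lt(max(abs(j1$centers - j1$nominal)), 1.4e-6 / 2 - j1$radius + 1e-12)
})

test_that("dipole-array mesh conforms and excludes the particle interiors", {
  dip <- make_dipole_grid(spacing = 2.5e-6)  # 4x4 grid, fast
  msh <- make_dipole_array_mesh(dip)
  mesh_audit(msh)
  A <- tri_areas(msh)
  expect_equal(sum(A),
               (10e-6)^2 - nrow(dip$centers) * pi * dip$radius^2,
               tolerance = 0.005)
  expect_setequal(unique(msh$subdomain), "gel")
  expect_length(boundary_nodes(msh, "particle_surface_1") > 0,
                length(boundary_nodes(msh, "particle_surface_1")))
  # every particle surface tag present
  tags <- grep("^particle_surface", unique(msh$btags), value = TRUE)
  expect_length(tags, nrow(dip$centers))
})

test_that("planar particle/rod mesh reproduces areas and rotations", {
  for (L in c(100e-9, 400e-9)) {
    msh <- make_hap_2d_mesh(hap_length = L)
    mesh_audit(msh)
    A <- tri_areas(msh)
    expect_equal(sum(A[msh$subdomain == "hap"]), 50e-9 * L,
                 tolerance = 0.01)
  }
  m0 <- make_hap_2d_mesh(hap_length = 100e-9, rotation_deg = 0)
  m90 <- make_hap_2d_mesh(hap_length = 100e-9, rotation_deg = 90)
  a0 <- sum(tri_areas(m0)[m0$subdomain == "hap"])
  a90 <- sum(tri_areas(m90)[m90$subdomain == "hap"])
  expect_equal(a0, a90, tolerance = 0.01)
  hb0 <- m0$nodes[boundary_nodes(m0, "hap_surface"), ]
  hb90 <- m90$nodes[boundary_nodes(m90, "hap_surface"), ]
  # bounding box extents swap under a quarter turn
  expect_equal(diff(range(hb0[, 1])), diff(range(hb90[, 2])), tolerance = 0.01)
  expect_equal(diff(range(hb0[, 2])), diff(range(hb90[, 1])), tolerance = 0.01)
  expect_error(make_hap_2d_mesh(hap_length = 520e-9), "collides")
})
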