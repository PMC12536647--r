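m3 <- make_3d_mesh("embedded")  # default resolution, shared across checks

test_that("3D mesh passes the conformity audit and conserves volume", {
  mesh_audit(m3)
  vol <- tet_volumes(m3)
  expect_true(all(vol > 0))
  sphere_vol <- 2 * (4 / 3) * pi * (70e-9)^3
  expect_equal(sum(vol), 1e-6 * 1e-6 * 2e-6 - sphere_vol, tolerance = 1e-3)
})

test_that("hexagonal rod volume matches the prism closed form within 2%", {
  a <- 50e-9 / sqrt(3)  # side from the 50 nm across-flats diameter
  v_closed <- (3 * sqrt(3) / 2) * a^2 * 100e-9
  expect_equal(sum(tet_volumes(m3)[m3$subdomain == "hap"]), v_closed,
               tolerance = 0.02)
})

test_that("sphere surfaces carry their tags and lie on the spheres", {
  for (i in 1:2) {
    sn <- boundary_nodes(m3, paste0("particle_surface_", i))
    expect_gt(length(sn), 50)
    ctr <- c(ifelse(i == 1, -0.325e-6, 0.325e-6), 0, -0.12e-6)
    r <- sqrt(rowSums(sweep(m3$nodes[sn, ], 2, ctr)^2))
    expect_lt(max(abs(r - 70e-9)), 1e-12)
  }
})
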