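test_that("subdomain summaries are volume-weighted means and maxima", {
  # two-tet toy mesh with known volumes (1/6 and 1/3 scaled)
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, -2))
  elem <- rbind(c(1, 2, 3, 4), c(1, 3, 2, 5))
  msh <- mp_mesh(nodes, elem, c("hap", "hap"),
                 matrix(c(1, 2, 3), 1), "outer_top", coord = "3d")
  vols <- abs(tet_volumes(msh))
  sol <- field_solution(msh, E = cbind(c(3, 9), 0, 0))
  s <- subdomain_field_summary(sol, "hap")
  expect_equal(s$max, 9)
  expect_equal(s$avg, sum(c(3, 9) * vols) / sum(vols))
  # uniform field: average equals maximum
  sol_u <- field_solution(msh, E = cbind(c(5, 5), 0, 0))
  su <- subdomain_field_summary(sol_u, "hap")
  expect_equal(su$avg, su$max)
  expect_error(subdomain_field_summary(sol, "cell"), "empty")
  # split partitions at the interface plane
  sp <- subdomain_field_summary(sol, "hap", split_by_neighbor = TRUE)
  expect_equal(sp$cell_side_max, 3)  # centroid z > 0 tet holds |E| = 3
  expect_equal(sp$gel_side_max, 9)
})

test_that("3D meshes realise the two configurations geometrically", {
  m_emb <- make_3d_mesh("embedded", h = 22e-9)
  zh <- range(m_emb$nodes[boundary_nodes(m_emb, "hap_surface"), 3])
  expect_equal(zh[2], -0.05e-6, tolerance = 1e-6)   # 0.05 um clearance
  expect_lt(max(elem_centroids(m_emb)[m_emb$subdomain == "hap", 3]), 0)
  m_int <- make_3d_mesh("interface", h = 22e-9)
  zc <- elem_centroids(m_int)[m_int$subdomain == "hap", 3]
  expect_true(any(zc > 0) && any(zc < 0))           # straddles the interface
  expect_error(make_3d_mesh("embedded", h = 30e-9), "too coarse")
})

test_that("coarse 3D chain honours its invariants", {
  r <- run_3d_stage("interface", list(h = 24e-9))
  expect_lte(r$E_avg_hap, r$E_max_hap)
  expect_gte(r$vm_cell_max, 0)
  expect_gte(r$vm_gel_max, 0)
  expect_gt(r$E_avg_hap, 0)
  # field on the rod portion in the less conductive gel exceeds the cell side
  expect_gte(r$E_gel_side_max, r$E_cell_side_max)
})
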