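test_that("magnetoelectric coefficient estimators are exact conversions", {
  # 300 mT in free space is 3000 Oe
  expect_equal(tesla_to_oersted(0.3), 3000)
  # border-field estimator: 3.3e4 V/m at 300 mT -> 0.11 V/cm/Oe
  expect_equal(me_coefficient_field(3.3e4, 0.3), 0.11)
  expect_equal(me_coefficient_field(0, 0.3), 0)
  expect_equal(me_coefficient_field(2 * 3.3e4, 0.3),
               2 * me_coefficient_field(3.3e4, 0.3))
  expect_error(me_coefficient_field(1e3, 0), "positive")
  # potential estimator: 2.72 mV across 140 nm at 300 mT -> 0.0648 V/cm/Oe
  expect_equal(me_coefficient_potential(2.72e-3, 0.3, 140e-9), 0.0647619,
               tolerance = 1e-6)
  expect_equal(me_coefficient_potential(0, 0.3, 140e-9), 0)
  expect_equal(me_coefficient_potential(1e-3, 0.3, 70e-9),
               2 * me_coefficient_potential(1e-3, 0.3, 140e-9))
  expect_error(me_coefficient_potential(1e-3, 0.3, 0), "diameter")
})

test_that("null magnetic drive produces a null chain", {
  res <- run_menp_stage(list(B = 0, h = 8e-9))
  expect_equal(res$max_core_M, 0)
  expect_equal(res$max_vonMises, 0)
  expect_equal(res$surface_V_amplitude, 0)
  expect_equal(res$alpha_ME_field, 0)
  expect_equal(res$alpha_ME_potential, 0)
})

res_default <- run_menp_stage(list(h = 6e-9))

test_that("single-particle chain satisfies its structural invariants", {
  expect_gt(res_default$surface_V_amplitude, 0)
  expect_true(is.finite(res_default$alpha_ME_field) &&
                res_default$alpha_ME_field > 0)
  expect_true(is.finite(res_default$alpha_ME_potential) &&
                res_default$alpha_ME_potential > 0)
  # the two estimators agree within a factor of two
  ratio <- res_default$alpha_ME_field / res_default$alpha_ME_potential
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
  # stress concentrates in the particle, not the far gel
  expect_true(res_default$max_vonMises_subdomain %in% c("core", "shell"))
})

test_that("potential is antisymmetric about the equatorial plane", {
  msh <- res_default$mesh; V <- res_default$fields$V
  up <- which(msh$nodes[, 2] > 1e-9)
  key <- sprintf("%.10e_%.10e", msh$nodes[, 1], -msh$nodes[, 2])
  key_up <- sprintf("%.10e_%.10e", msh$nodes[up, 1], msh$nodes[up, 2])
  mirror <- match(key_up, key)
  ok <- !is.na(mirror)
  expect_gt(mean(ok), 0.95)  # the lattice is mirror-symmetric
  amp <- max(abs(V))
  # a few percent of mirror asymmetry from the triangulation is tolerated
  expect_lt(max(abs(V[up][ok] + V[mirror[ok]])), 0.05 * amp)
})

test_that("gel field decays with distance and spans the reported band", {
  pr <- res_default$E_profile
  eq <- pr$E_mag[pr$ray == "equatorial"]
  # monotone decrease along the equatorial ray (small element-wise jitter
  # from the piecewise-constant field is tolerated)
  expect_true(all(diff(eq) < 0.02 * eq[-length(eq)]))
  expect_gt(eq[1], 1e4)
  expect_lt(eq[length(eq)], 1e3)
})
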