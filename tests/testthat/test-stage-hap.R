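test_that("representative strain is the projected displacement-length ratio", {
  expect_equal(strain_from_displacement(c(0, 0), c(0, 1e-9), c(0, 1), 100e-9),
               0.01)
  expect_equal(strain_from_displacement(c(1e-9, 2e-9), c(1e-9, 2e-9),
                                        c(0, 1), 100e-9), 0)
  # same end displacement, four times the length: quarter of the strain
  expect_equal(strain_from_displacement(c(0, 0), c(0, 1e-9), c(0, 1), 400e-9),
               strain_from_displacement(c(0, 0), c(0, 1e-9), c(0, 1), 100e-9) / 4)
  expect_error(strain_from_displacement(c(0, 0), c(0, 1), c(0, 1), 0),
               "positive")
})

hr <- run_hap_stage(100e-9, 0)

test_that("particle response satisfies its structural invariants", {
  expect_lte(hr$vm_hap_avg, hr$vm_hap_max)
  expect_gte(hr$vm_gel_max, 0)
  expect_gt(diff(hr$V_hap), 0)          # nonzero potential range
  expect_gt(hr$u_max, 0)
  expect_gte(hr$strain_repr, 0)
})

test_that("zero piezoelectric coupling gives a null mechanical response", {
  h0 <- run_hap_stage(100e-9, 0, zero_piezo = TRUE)
  expect_equal(h0$u_max, 0)
  expect_equal(h0$vm_hap_max, 0)
  expect_equal(h0$vm_gel_max, 0)
})

test_that("the fully linear chain scales with the dipole amplitude", {
  h2 <- run_hap_stage(100e-9, 0, config = list(V0 = 2 * 1.36e-3))
  expect_equal(h2$u_max / hr$u_max, 2, tolerance = 0.01)
  expect_equal(h2$vm_hap_max / hr$vm_hap_max, 2, tolerance = 0.01)
  expect_equal(h2$vm_gel_max / hr$vm_gel_max, 2, tolerance = 0.01)
  expect_equal(diff(h2$V_hap) / diff(hr$V_hap), 2, tolerance = 0.01)
})

test_that("a longer particle shows a wider polarization range", {
  h4 <- run_hap_stage(400e-9, 0)
  expect_gt(diff(h4$V_hap), diff(hr$V_hap))
})
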