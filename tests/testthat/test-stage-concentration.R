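test_that("coverage fractions follow the area-weighted definition", {
  # uniform field between two thresholds
  expect_equal(unname(coverage_fraction(rep(500, 10), rep(1, 10))),
               c(1, 1, 0, 0, 0))
  # log-spaced samples with equal weights against a hand count
  s <- 10^(0:6)
  expect_equal(unname(coverage_fraction(s, rep(1, 7))),
               c(5, 4, 3, 2, 1) / 7)
  # area weighting
  expect_equal(unname(coverage_fraction(c(1e4, 1), c(3, 1))[1]), 0.75)
  expect_error(coverage_fraction(numeric(0), numeric(0)), "empty")
  expect_error(coverage_fraction(1:3, c(1, -1, 1)), "positive")
  # monotone in the threshold for random fields
  set.seed(5)
  for (k in 1:5) {
    f <- coverage_fraction(10^runif(200, 0, 6), runif(200, 0.1, 1))
    expect_true(all(diff(f) <= 0))
  }
})

test_that("3D volume-fraction estimate matches the closed form", {
  expect_equal(volume_fraction_3d(1.0e-6), 0.1437, tolerance = 1e-3)
  expect_equal(volume_fraction_3d(11e-6), 0)    # nothing fits
  expect_equal(volume_fraction_3d(2e-6, particle_radius = 0.14e-6) /
                 volume_fraction_3d(2e-6, particle_radius = 0.07e-6), 8,
               tolerance = 1e-12)
})

test_that("null dipole amplitude gives a null field everywhere", {
  cs <- run_concentration_stage(2.5e-6, V0 = 0)
  expect_true(all(cs$area_fraction_above == 0))
  expect_lt(cs$E_max, 1e-12)
})

test_that("an isolated dipole reproduces the analytic exceedance area", {
  cs <- run_concentration_stage(6e-6, delta = 0.5e-6, h = 20e-9)
  expect_equal(cs$n_particles, 1)
  a <- 70e-9; V0 <- cs$V0
  thr <- 1e3
  r_t <- sqrt(V0 * a / thr)   # |E| = V0 a / r^2 for the planar disc dipole
  frac_pred <- pi * (r_t^2 - a^2) / ((10e-6)^2 - pi * a^2)
  expect_equal(unname(cs$area_fraction_above[3]), frac_pred, tolerance = 0.05)
})

test_that("coverage is reproducible and increases with concentration", {
  c1 <- run_concentration_stage(2.0e-6)
  c2 <- run_concentration_stage(2.0e-6)
  expect_identical(c1$area_fraction_above, c2$area_fraction_above)
  c3 <- run_concentration_stage(1.2e-6)
  expect_true(all(c3$area_fraction_above[2:4] >= c1$area_fraction_above[2:4]))
})
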