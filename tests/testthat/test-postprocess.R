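test_that("comparison table applies tiered tolerances and flags gaps", {
  cmp <- compare_to_reference(list(alpha_ME_potential = 0.065))
  row <- cmp[cmp$quantity == "alpha_ME_potential", ]
  expect_equal(row$status, "pass")   # 0.065 vs 0.07 within the tight 10%
  expect_equal(cmp$status[cmp$quantity == "max_core_M"], "not computed")
  # every reference quantity gets a row; coverage rows measured in points
  expect_true(all(reference_values()$quantity %in% cmp$quantity))
  cmp2 <- compare_to_reference(list(`coverage_0.65um_1e3` = 91.00))
  expect_equal(cmp2$status[cmp2$quantity == "coverage_0.65um_1e3"], "pass")
  cmp3 <- compare_to_reference(list(`coverage_0.65um_1e3` = 80.00))
  expect_equal(cmp3$status[cmp3$quantity == "coverage_0.65um_1e3"], "fail")
})

test_that("reference coverage table carries the six studied spacings", {
  tab <- coverage_reference_table()
  expect_equal(nrow(tab), 6)
  expect_equal(tab$spacing_um, c(1.40, 1.00, 0.90, 0.80, 0.70, 0.65))
  # printed fractions are monotone in both directions
  for (k in 2:5) {
    expect_true(all(tab[[paste0("pct_above_1e", k)]] <=
                      tab[[paste0("pct_above_1e", k - 1)]]))
  }
})

test_that("VTK export writes a readable unstructured grid", {
  msh <- rect_grid_mesh(c(0, 1e-6), c(0, 1e-6), 3, 3)
  f <- tempfile(fileext = ".vtk")
  write_vtk(msh, f, point_data = list(V = seq_len(nrow(msh$nodes))),
            cell_data = list(q = seq_len(nrow(msh$elem))))
  lines <- readLines(f)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_true(any(grepl("^POINTS 16 double", lines)))
  expect_true(any(grepl("^CELLS 18 72", lines)))
  expect_true(any(grepl("SCALARS V double", lines)))
  unlink(f)
})

test_that("stage outputs land in the requested directory deterministically", {
  d1 <- tempfile(); d2 <- tempfile()
  run_concentration_stage(2.5e-6, out_dir = d1)
  run_concentration_stage(2.5e-6, out_dir = d2)
  f1 <- file.path(d1, "coverage_2.50um_uniform.csv")
  f2 <- file.path(d2, "coverage_2.50um_uniform.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("run configuration loads with the documented schema", {
  cfg <- default_run_config()
  expect_equal(cfg$schema_version, 1)
  expect_equal(cfg$menp$B, 0.3)
  expect_length(cfg$concentration$spacings_um, 6)
  expect_null(cfg$V0_override)
})
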