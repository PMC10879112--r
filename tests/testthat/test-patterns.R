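test_that("pattern specifications validate their parameters", {
  expect_error(pattern_spec(0, 1.5), "period")
  expect_error(pattern_spec(0, 4, duty = 0), "duty")
  expect_error(pattern_spec(0, 4, duty = 1), "duty")
  expect_error(pattern_spec(0, 4, phase_index = 3, n_phases = 3),
               "phase_index")
  expect_s3_class(pattern_spec(60, 4, 1, 3), "pattern_spec")
})

test_that("rasterized line patterns are binary with the documented geometry", {
  m <- make_line_pattern(pattern_spec(0, 4, 0, 4, duty = 0.5), c(8, 8))
  expect_true(all(m %in% c(0L, 1L)))
  # angle 0: intensity varies along rows; rows 1,2 on, 3,4 off, ...
  expect_equal(rowSums(m), c(8, 8, 0, 0, 8, 8, 0, 0))
  mv <- make_line_pattern(pattern_spec(90, 4, 0, 4, duty = 0.5), c(8, 8))
  expect_equal(mv, t(m))
  expect_error(make_line_pattern(pattern_spec(0, 4), c(4, 4)), "8 x 8")
})

test_that("phase stepping shifts the pattern by whole sub-period steps", {
  s0 <- make_line_pattern(pattern_spec(0, 4, 0, 4), c(16, 16))
  s1 <- make_line_pattern(pattern_spec(0, 4, 1, 4), c(16, 16))
  # one phase step of a 4-px period with 4 phases = 1 px along the normal
  expect_equal(s1[2:16, ], s0[1:15, ])
})

test_that("mark-to-area ratio requires binary masks and equals the on-fraction", {
  m <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(mark_to_area_ratio(m), 0.25)
  expect_error(mark_to_area_ratio(matrix(0.5, 2, 2)), "binary")
})

test_that("every phase mask of the 12-pattern repertoire has identical duty", {
  mars <- vapply(build_repertoire("bio12")$masks, mark_to_area_ratio,
                 numeric(1))
  expect_equal(mars, rep(0.25, 12))
})

test_that("summed illumination of each preset tiles the field exactly", {
  for (p in c("minimal9", "bio12", "fixed14")) {
    expect_equal(homogeneity_residual(build_repertoire(p, c(160, 160))), 0,
                 info = p)
  }
})

test_that("mean mark-to-area ratio is matched across orientations", {
  expect_equal(mar_uniformity(build_repertoire("minimal9", c(160, 160))), 0)
  expect_equal(mar_uniformity(build_repertoire("bio12", c(160, 160))), 0)
  # diagonal rasters cannot match the axis-aligned duty exactly; the
  # documented tolerance is 0.1
  expect_lte(mar_uniformity(build_repertoire("fixed14", c(160, 160))), 0.1)
})

test_that("diagonal orientations use lattice-representable periods", {
  seq14 <- build_repertoire("fixed14", c(160, 160))
  periods <- vapply(seq14$specs, `[[`, numeric(1), "period")
  angles <- vapply(seq14$specs, `[[`, numeric(1), "angle")
  diag_p <- unique(periods[angles %in% c(45, 135)])
  # period * sqrt(2) must be integer (projection step of the pixel lattice)
  expect_equal(diag_p * sqrt(2), round(diag_p * sqrt(2)))
})

test_that("repertoire export and re-import is lossless", {
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, sidecar_path(path))), add = TRUE)
  seq_ <- build_repertoire("bio12", c(160, 160))
  write_repertoire(seq_, path)
  back <- read_repertoire(path)
  expect_equal(length(back), 12)
  for (i in seq_along(seq_$masks)) {
    expect_equal(back$masks[[i]], seq_$masks[[i]])
  }
  expect_equal(back$specs, seq_$specs)
  expect_equal(back$preset, "bio12")
})

test_that("repertoire import rejects a page count that contradicts the sidecar", {
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, sidecar_path(path))), add = TRUE)
  seq_ <- build_repertoire("minimal9", c(160, 160))
  write_repertoire(seq_, path)
  meta <- yaml::read_yaml(sidecar_path(path))
  meta$patterns <- meta$patterns[1:5]
  yaml::write_yaml(meta, sidecar_path(path))
  expect_error(read_repertoire(path), "page count")
})
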