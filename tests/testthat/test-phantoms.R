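test_that("bead fields respect count, margin and minimum separation", {
  ph <- generate_bead_phantom(8, c(128, 128), 65, min_separation = 1200,
                              margin = 1200, seed = 3)
  expect_equal(nrow(ph$positions), 8)
  d <- as.matrix(dist(ph$positions))
  diag(d) <- Inf
  expect_gte(min(d), 1200)
  fov <- 127 * 65
  expect_true(all(ph$positions >= 1200 & ph$positions <= fov - 1200))
  expect_true(all(ph$density %in% c(0, 1)))
  expect_gt(sum(ph$density), 0)
})

test_that("bead placement is reproducible from the seed", {
  a <- generate_bead_phantom(5, c(128, 128), 65, seed = 9,
                             min_separation = 1500, margin = 1500)
  b <- generate_bead_phantom(5, c(128, 128), 65, seed = 9,
                             min_separation = 1500, margin = 1500)
  c_ <- generate_bead_phantom(5, c(128, 128), 65, seed = 10,
                              min_separation = 1500, margin = 1500)
  expect_identical(a$positions, b$positions)
  expect_false(isTRUE(all.equal(a$positions, c_$positions)))
})

test_that("impossible bead packings are refused", {
  expect_error(
    generate_bead_phantom(100, c(64, 64), 65, min_separation = 2000,
                          margin = 200, max_attempts = 200),
    "could not place")
  expect_error(generate_bead_phantom(2, c(16, 16), 65,
                                     min_separation = 2000), "too small")
})

test_that("bead pairs sit symmetrically at the requested separation", {
  ph <- generate_bead_pair(200, c(128, 128), 65)
  expect_equal(nrow(ph$positions), 2)
  expect_equal(sqrt(sum((ph$positions[1, ] - ph$positions[2, ])^2)), 200)
  ctr <- (c(128, 128) - 1) / 2 * 65
  expect_equal(colMeans(ph$positions), ctr, ignore_attr = TRUE)
  expect_error(generate_bead_pair(30, c(128, 128), 65), "pixel")
})

test_that("a background plane requires a strictly positive defocus", {
  m <- matrix(1, 16, 16)
  expect_error(phantom(m, 65, background = m), "defocus")
  expect_error(phantom(m, 65, background = m, defocus = 0), "defocus")
  expect_s3_class(phantom(m, 65, background = m, defocus = 1000), "phantom")
  expect_error(phantom(m, 65, background = matrix(1, 8, 8),
                       defocus = 1000), "shape")
  expect_error(phantom(matrix(-1, 4, 4), 65), ">= 0")
})
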