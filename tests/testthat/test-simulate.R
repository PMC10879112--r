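test_that("projected patterns stay in [0,1] and keep their mean dose", {
  mask <- make_line_pattern(pattern_spec(0, 4, 0, 4), c(160, 160))
  illum <- project_pattern(mask, optical_config())
  expect_equal(dim(illum), c(128, 128))
  expect_true(all(illum >= 0 & illum <= 1))
  expect_equal(mean(illum), mean(mask), tolerance = 1e-10)
})

test_that("projection attenuates the pattern fundamental by the incoherent OTF", {
  cfg <- optical_config()
  mask <- make_line_pattern(pattern_spec(0, 4, 0, 2, duty = 0.5),
                            c(160, 160))
  illum <- project_pattern(mask, cfg)
  k_nm <- 1 / (4 * slm_sample_pixel(cfg))   # pattern fundamental, cycles/nm
  m_in <- 2 * Mod(incosim:::dft_at(mask, 0, k_nm,
                                   slm_sample_pixel(cfg))) / sum(mask)
  m_out <- 2 * Mod(incosim:::dft_at(illum, 0, k_nm,
                                    sample_pixel(cfg))) / sum(illum)
  rho <- k_nm * 1000 / widefield_cutoff(cfg, "excitation")
  expect_equal(m_out / m_in, incoherent_otf(rho), tolerance = 1e-9)
})

test_that("non-binary masks and incommensurate grids are rejected", {
  cfg <- optical_config()
  expect_error(project_pattern(matrix(0.5, 160, 160), cfg), "binary")
  expect_error(project_pattern(matrix(0L, 9, 9), cfg), "commensurate")
})

test_that("acquisition is bit-reproducible for a fixed seed", {
  a <- simulate_acquisition(fixture_phantom, fixture_seq, fixture_config,
                            noise_model(1e4, 2, seed = 12))
  expect_identical(a$frames, fixture_stack$frames)
  b <- simulate_acquisition(fixture_phantom, fixture_seq, fixture_config,
                            noise_model(1e4, 2, seed = 13))
  expect_false(identical(b$frames, fixture_stack$frames))
})

test_that("the photon scale anchors the noise-free widefield peak", {
  wf <- widefield_from_stack(fixture_stack_clean)
  expect_equal(max(wf), 1e4, tolerance = 1e-10)
})

test_that("phantom/configuration mismatches are diagnosed", {
  cfg <- optical_config()
  bad_pixel <- phantom(matrix(1, 128, 128), 60)
  expect_error(simulate_acquisition(bad_pixel, fixture_seq, cfg),
               "pixel")
  bad_shape <- phantom(matrix(1, 64, 64), sample_pixel(cfg))
  expect_error(simulate_acquisition(bad_shape, fixture_seq, cfg),
               "does not match")
})

test_that("a deeply defocused plane receives unmodulated illumination", {
  cfg <- optical_config()
  focal <- matrix(0, 128, 128)
  backg <- matrix(0, 128, 128)
  backg[40:88, 40:88] <- 1
  ph <- generate_two_plane_phantom(focal, backg, 1600, sample_pixel(cfg))
  st <- simulate_acquisition(ph, fixture_seq, cfg,
                             noise_model(1e4, 0, seed = 1,
                                         shot_noise = FALSE))
  # with no in-focus structure, all frames must be (nearly) identical:
  # the pattern modulation is wiped out by the defocus transfer
  spread <- Reduce(pmax, st$frames) - Reduce(pmin, st$frames)
  expect_lt(max(spread) / max(st$frames[[1]]), 1e-3)
})
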