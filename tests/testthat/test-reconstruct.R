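test_that("band separation inverts the phase-mixing model to 1e-10", {
  set.seed(21)
  n <- 32
  S0 <- matrix(runif(n * n), n, n)
  Z <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  phases <- c(0, 2 * pi / 3, 4 * pi / 3) + 0.3
  frames <- lapply(phases, function(p) {
    Re(S0 + Z * exp(1i * p) + Conj(Z) * exp(-1i * p))
  })
  bands <- separate_bands(frames, phases)
  expect_lt(max(Mod(bands$S0 - S0)), 1e-10)
  expect_lt(max(Mod(bands$S_plus - Z)), 1e-10)
  expect_lt(max(Mod(bands$S_minus - Conj(Z))), 1e-10)
})

test_that("degenerate phase sets are rejected as singular", {
  frames <- replicate(3, matrix(1, 4, 4), simplify = FALSE)
  expect_error(separate_bands(frames, c(0, 0, 2)), "degenerate")
  expect_error(separate_bands(frames[1:2], c(0, 1)), ">= 3")
})

test_that("pattern frequency and phases are recovered from raw frames", {
  pars <- estimate_pattern_parameters(fixture_stack)
  cfg <- fixture_config
  k_nom <- 1 / (4 * slm_sample_pixel(cfg)) * 1000   # cycles/um
  for (p in pars) {
    expect_lt(abs(p$k_mag - k_nom) / k_nom, 0.01)
    expect_gt(p$strength, 4)
    expect_gt(p$coherence, 0.7)
    steps <- diff(p$phases) %% (2 * pi)
    # bio12: four phases stepped by -90 degrees
    expect_equal(steps, rep(3 * pi / 2, 3), tolerance = 1e-6)
  }
})

test_that("unmodulated stacks yield no significant pattern peak", {
  flat <- fixture_stack
  wf <- widefield_from_stack(fixture_stack)
  flat$frames <- lapply(flat$frames, function(f) wf)
  expect_error(estimate_pattern_parameters(flat), "no pattern modulation")
})

test_that("widefield equivalent is the mean over the pattern sequence", {
  wf <- widefield_from_stack(fixture_stack)
  expect_equal(wf, Reduce(`+`, fixture_stack$frames) / 12)
})

test_that("super-resolution reconstruction demands 3 orientations and 3 phases", {
  one_angle <- simulate_acquisition(
    phantom(fixture_phantom$density, fixture_phantom$pixel),
    fixture_seq_one_angle, fixture_config, noise_model(1e4, 2, seed = 4))
  expect_error(reconstruct_sr_sim(one_angle), ">= 3 pattern orientations")
  two_phase <- fixture_stack
  keep <- c(1, 2, 5, 6, 9, 10)
  two_phase$frames <- two_phase$frames[keep]
  two_phase$sequence$masks <- two_phase$sequence$masks[keep]
  two_phase$sequence$specs <- two_phase$sequence$specs[keep]
  expect_error(reconstruct_sr_sim(two_phase), ">= 3 phases")
  expect_error(reconstruct_os_sim(two_phase), ">= 3 phases")
})

test_that("reconstruction doubles the pixel grid and reports its passband", {
  sr <- reconstruct_sr_sim(fixture_stack)
  expect_equal(dim(sr$image), c(256, 256))
  expect_equal(sr$pixel, sample_pixel(fixture_config) / 2)
  k_est <- max(vapply(sr$k_est, function(k) sqrt(sum(k^2)), numeric(1)))
  expect_equal(sr$passband_radius,
               k_est + widefield_cutoff(fixture_config, "emission"))
})

test_that("estimated and nominal pattern parameters give matching images", {
  sr_est <- reconstruct_sr_sim(fixture_stack)
  sr_meta <- reconstruct_sr_sim(fixture_stack,
                                recon_params(phase_source = "metadata"))
  expect_gt(cor(as.vector(sr_est$image), as.vector(sr_meta$image)), 0.99)
})

test_that("sectioned images are non-negative and noise-bias aware", {
  os <- reconstruct_os_sim(fixture_stack)
  expect_true(all(os$image >= 0))
  expect_match(os$method, "corrected")
  # noise-free stacks skip the correction automatically
  os_clean <- reconstruct_os_sim(fixture_stack_clean)
  expect_false(grepl("corrected", os_clean$method))
  expect_identical(
    reconstruct_os_sim(fixture_stack_clean, bias_correction = FALSE)$image,
    os_clean$image)
})

test_that("square-law output is invariant to the phase origin", {
  # shifting which phase comes first permutes frames within an orientation;
  # the pooled pairwise differences are unchanged
  rolled <- fixture_stack
  perm <- c(2, 3, 4, 1, 6, 7, 8, 5, 10, 11, 12, 9)
  rolled$frames <- rolled$frames[perm]
  rolled$sequence$masks <- rolled$sequence$masks[perm]
  expect_equal(reconstruct_os_sim(rolled)$image,
               reconstruct_os_sim(fixture_stack)$image)
})
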