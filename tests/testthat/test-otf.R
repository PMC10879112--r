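test_that("incoherent OTF matches the closed form of the chat function", {
  expect_equal(incoherent_otf(0), 1)
  expect_equal(incoherent_otf(1), 0)
  expect_equal(incoherent_otf(0.5),
               (2 / pi) * (acos(0.5) - 0.5 * sqrt(0.75)))
  rhos <- seq(0, 0.999, length.out = 200)
  vals <- incoherent_otf(rhos)
  expect_true(all(diff(vals) < 0))            # strictly decreasing
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(incoherent_otf(c(1.2, 5)), c(0, 0))  # zero beyond cutoff
})

test_that("negative normalized frequencies are rejected", {
  expect_error(incoherent_otf(-0.1), ">= 0")
  expect_error(pattern_contrast_curve(c(0.5, -1)), ">= 0")
})

test_that("coherent fringe contrast is frequency independent below cutoff", {
  rhos <- seq(0.05, 0.95, by = 0.1)
  expect_equal(pattern_contrast_curve(rhos, "coherent"),
               rep(1, length(rhos)))
  expect_equal(pattern_contrast_curve(1.5, "coherent"), 0)
})

test_that("widefield cutoffs follow 2 NA / lambda for both wavelengths", {
  cfg <- optical_config()
  expect_equal(widefield_cutoff(cfg, "emission"), 2 * 1.3 / 0.515)
  expect_equal(widefield_cutoff(cfg, "excitation"), 2 * 1.3 / 0.460)
  expect_gt(widefield_cutoff(cfg, "excitation"),
            widefield_cutoff(cfg, "emission"))
})

test_that("PSF from the OTF is a normalized, centred convolution kernel", {
  cfg <- optical_config()
  psf <- psf_from_otf(otf_model(cfg, "emission"), c(64, 64), 32.5)
  expect_equal(sum(psf), 1)
  expect_true(all(psf >= 0))
  peak <- which(psf == max(psf), arr.ind = TRUE)[1, ]
  expect_equal(as.integer(peak), c(33L, 33L))  # grid centre
})

test_that("undersampled PSF grids are refused with a diagnosis", {
  cfg <- optical_config()
  expect_error(psf_from_otf(otf_model(cfg, "emission"), c(64, 64), 130),
               "undersampled")
})
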