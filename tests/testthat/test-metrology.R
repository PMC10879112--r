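test_that("Gaussian FWHM fitting recovers a known peak width", {
  pixel <- 65
  sigma_px <- 1.4
  x <- outer(rep(1, 41), 1:41)
  y <- t(x)
  img <- 10 + 80 * exp(-((x - 21.3)^2 + (y - 20.6)^2) / (2 * sigma_px^2))
  fwhm <- fit_gaussian_fwhm(img, c(21, 21), pixel, window = 8)
  expect_equal(fwhm, 2 * sqrt(2 * log(2)) * sigma_px * pixel,
               tolerance = 1e-6)
})

test_that("featureless windows cannot be fitted", {
  expect_error(fit_gaussian_fwhm(matrix(3, 41, 41), c(21, 21), 65), "flat")
})

test_that("bead reports average the successful fits and list failures", {
  pixel <- 65
  x <- outer(rep(1, 64), 1:64)
  y <- t(x)
  img <- exp(-((x - 16)^2 + (y - 16)^2) / (2 * 1.5^2)) +
    exp(-((x - 48)^2 + (y - 48)^2) / (2 * 1.5^2))
  pos <- rbind(c(16, 16), c(48, 48), c(32, 16))   # third is empty space
  rep_ <- mean_fwhm_over_beads(img, pos, pixel)
  expect_equal(rep_$n, 2)
  expect_equal(rep_$excluded, 3L)
  expect_equal(rep_$mean, mean(rep_$per_bead))
  expect_error(mean_fwhm_over_beads(matrix(1, 64, 64), pos, pixel),
               "all bead fits failed")
})

test_that("the dip criterion separates double from single peaks", {
  x <- outer(rep(1, 64), 1:64)
  y <- t(x)
  g <- function(r, c) exp(-((y - r)^2 + (x - c)^2) / (2 * 2^2))
  two <- g(32, 24) + g(32, 40)
  res <- pair_resolved(two, c(32, 24), c(32, 40))
  expect_true(res$resolved)
  expect_gt(res$dip, 0.5)
  one <- g(32, 31) + g(32, 33)    # separation well below the width
  expect_false(pair_resolved(one, c(32, 31), c(32, 33))$resolved)
  expect_error(pair_resolved(two, c(32, 24), c(32, 24)), "coincide")
})

test_that("spectral support tracks the band limit of an image", {
  cfg <- optical_config()
  cutoff <- widefield_cutoff(cfg, "emission")
  set.seed(5)
  noise <- matrix(rnorm(128 * 128), 128, 128)
  H <- incosim:::otf_grid(128, 128, 65, cutoff / 1000)
  limited <- Re(incosim:::ifft2(incosim:::fft2(noise) * H))
  # a small detection-noise floor, as any recorded image has; without it
  # the out-of-band spectrum is pure floating-point roundoff
  limited <- limited + 1e-5 * sd(limited) * matrix(rnorm(128 * 128), 128)
  sup <- radial_spectrum_support(limited, 65)
  expect_lt(sup, cutoff * 1.05)
  expect_gt(sup, cutoff * 0.6)
  # white noise has no band limit: support reaches the Nyquist radius
  sup_white <- radial_spectrum_support(noise, 65)
  expect_gt(sup_white, 0.95 * 1000 / (2 * 65))
  expect_error(radial_spectrum_support(matrix(1, 128, 128), 65), "constant")
  expect_error(radial_spectrum_support(matrix(rnorm(100), 10, 10), 65),
               "64 x 64")
})

test_that("maximum intensity projection is the pixelwise envelope", {
  a <- matrix(1:4, 2, 2)
  b <- matrix(4:1, 2, 2)
  expect_equal(max_intensity_projection(list(a, b)),
               matrix(c(4, 3, 3, 4), 2, 2))
  arr <- array(c(a, b), dim = c(2, 2, 2))
  expect_equal(max_intensity_projection(arr),
               max_intensity_projection(list(a, b)))
  expect_error(max_intensity_projection(list()), "no planes")
})
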