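#' Incoherent optical transfer function of a circular aperture
#'
#' Radial profile of the diffraction-limited incoherent OTF (the "chat"
#' function, the autocorrelation of a circular pupil):
#' `H(rho) = (2/pi) * (acos(rho) - rho * sqrt(1 - rho^2))` for
#' `rho <= 1` and 0 beyond, with `rho = nu / nu_c` the spatial frequency
#' normalized to the cutoff `nu_c = 2 NA / lambda`.
#'
#' This exact form, rather than a Gaussian approximation, matters here:
#' when the illumination pattern is an image of the SLM formed with
#' spatially incoherent LED light, the pattern contrast in the sample plane
#' is attenuated by exactly this function, falling towards zero as the
#' pattern frequency approaches the excitation cutoff.
#'
#' @param rho Normalized spatial frequency, `>= 0` (vectorized).
#' @return Contrast values in `[0, 1]`.
#' @examples
#' incoherent_otf(0)    # 1
#' incoherent_otf(1)    # 0
#' incoherent_otf(0.5)  # 0.3910
#' @export
incoherent_otf <- function(rho) {
  if (!is.numeric(rho)) stop("`rho` must be numeric", call. = FALSE)
  if (any(rho < 0)) {
    stop("normalized frequency `rho` must be >= 0", call. = FALSE)
  }
  out <- numeric(length(rho))
  inside <- rho < 1
  r <- rho[inside]
  out[inside] <- (2 / pi) * (acos(r) - r * sqrt(1 - r^2))
  dim(out) <- dim(rho)
  out
}

#' Pattern contrast versus spatial frequency, coherent vs incoherent
#'
#' For interference-based (coherent) SIM the fringe contrast is independent
#' of the fringe frequency up to the coherent limit; for SIM that images an
#' SLM into the sample with incoherent light, the contrast follows the
#' incoherent OTF and decays with frequency.  This curve is the quantitative
#' form of the design trade-off between the two illumination strategies.
#'
#' @param rhos Normalized frequencies (>= 0).
#' @param mode `"incoherent"` or `"coherent"`.
#' @return Contrast values, same length as `rhos`.
#' @export
pattern_contrast_curve <- function(rhos, mode = c("incoherent", "coherent")) {
  mode <- match.arg(mode)
  if (any(rhos < 0)) {
    stop("normalized frequencies must be >= 0", call. = FALSE)
  }
  switch(mode,
         incoherent = incoherent_otf(rhos),
         coherent = as.numeric(rhos < 1))
}

#' Radial OTF model bound to an optical configuration
#'
#' @param config An [optical_config()].
#' @param role `"emission"` or `"excitation"` -- selects the wavelength and
#'   hence the cutoff.
#' @return An object of class `otf_model` with the cutoff in cycles/um.
#' @export
otf_model <- function(config, role = c("emission", "excitation")) {
  role <- match.arg(role)
  structure(
    list(cutoff = widefield_cutoff(config, role), role = role,
         na = config$na),
    class = "otf_model"
  )
}

# Sampled OTF on a 2D FFT frequency grid (internal).  `cutoff_nm` in
# cycles/nm, `d` the pixel pitch in nm.
otf_grid <- function(nr, nc, d, cutoff_nm, kx = 0, ky = 0) {
  incoherent_otf(freq_radius(nr, nc, d, kx, ky) / cutoff_nm)
}

#' Point spread function from a radial OTF
#'
#' Inverse Fourier transform of the sampled radial incoherent OTF.  The
#' result is clipped of numerical ringing (|value| < 1e-9 of the maximum is
#' set to zero, small negative residuals are zeroed) and normalized to unit
#' sum, so it can be used directly as a convolution kernel.
#'
#' @param model An [otf_model()].
#' @param shape Integer vector `c(rows, cols)` of the output grid.
#' @param pixel Grid pixel size in nm.  Must satisfy the Nyquist condition
#'   `pixel < 1 / (2 * cutoff)`; otherwise the OTF support folds over and
#'   an error is raised.
#' @return A real, non-negative matrix summing to 1, with the PSF peak at
#'   the grid centre.
#' @export
psf_from_otf <- function(model, shape, pixel) {
  stopifnot(inherits(model, "otf_model"), length(shape) == 2)
  cutoff_nm <- model$cutoff / 1000
  nyquist <- 1 / (2 * pixel)
  if (nyquist <= cutoff_nm) {
    stop(sprintf(paste0(
      "grid undersampled: pixel = %.1f nm gives Nyquist %.4g cycles/nm ",
      "<= OTF cutoff %.4g cycles/nm; need pixel < %.1f nm"),
      pixel, nyquist, cutoff_nm, 1 / (2 * cutoff_nm)), call. = FALSE)
  }
  H <- otf_grid(shape[1], shape[2], pixel, cutoff_nm)
  psf <- Re(ifft2(H))
  psf <- fftshift2(psf)
  psf[abs(psf) < 1e-9 * max(psf)] <- 0
  psf[psf < 0] <- 0
  psf / sum(psf)
}
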