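#' Camera noise model
#'
#' Shot noise (Poisson) plus Gaussian read noise, with the absolute photon
#' scale set by `peak_photons`: the expected photon count at the brightest
#' pixel of the noise-free widefield image.
#'
#' @param peak_photons Peak widefield signal in photons (>= 0).
#' @param read_sigma Gaussian read noise RMS in photons (>= 0).
#' @param seed RNG seed; identical seeds give bit-identical frames.
#' @param shot_noise If `FALSE`, the Poisson step is skipped and frames are
#'   the noise-free expectations (useful for oracle comparisons).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(peak_photons = 1e4, read_sigma = 2, seed = 1,
                        shot_noise = TRUE) {
  stopifnot(peak_photons >= 0, read_sigma >= 0)
  structure(list(peak_photons = peak_photons, read_sigma = read_sigma,
                 seed = as.integer(seed), shot_noise = isTRUE(shot_noise)),
            class = "noise_model")
}

# Shape of the camera sample grid corresponding to an SLM mask: both cover
# the same field of view, so n_out = n_slm * slm_sample_pixel/sample_pixel
# must be (near-)integer.
sample_grid_shape <- function(mask_shape, config) {
  ratio <- slm_sample_pixel(config) / sample_pixel(config)
  n_out <- mask_shape * ratio
  if (any(abs(n_out - round(n_out)) > 1e-6)) {
    stop(sprintf(paste0(
      "SLM and camera sample grids are not commensurate: %d x %d SLM px ",
      "maps to %.3f x %.3f camera px; choose an SLM region whose size ",
      "times slm_pixel/camera_pixel is integer"),
      mask_shape[1], mask_shape[2], n_out[1], n_out[2]), call. = FALSE)
  }
  as.integer(round(n_out))
}

#' Project a binary SLM mask into the sample plane
#'
#' The mask is band-limited resampled (Fourier crop over the common field
#' of view) onto the camera sample grid and filtered by the
#' excitation-wavelength incoherent OTF -- the physical model of imaging an
#' incoherently illuminated SLM into the sample plane.  The DC component
#' (mean illumination) is preserved exactly; pattern harmonics beyond the
#' excitation cutoff are removed, and the fundamental is attenuated by
#' `incoherent_otf(k / k_cutoff_ex)`.
#'
#' @param mask Binary SLM mask.
#' @param config An [optical_config()].
#' @return Illumination map in `[0, 1]` on the sample grid, with the
#'   per-pixel grid size given by `sample_pixel(config)`.
#' @export
project_pattern <- function(mask, config) {
  if (!all(mask %in% c(0, 1))) {
    stop("`mask` must be strictly binary (0/1)", call. = FALSE)
  }
  stopifnot(inherits(config, "optical_config"))
  out_shape <- sample_grid_shape(dim(mask), config)
  d_slm <- slm_sample_pixel(config)
  d_out <- sample_pixel(config)
  cutoff_nm <- widefield_cutoff(config, "excitation") / 1000
  nyq_out <- 1 / (2 * d_out)
  if (cutoff_nm > nyq_out) {
    stop(sprintf(paste0(
      "excitation OTF support (%.4g cycles/nm) exceeds the sample-grid ",
      "Nyquist frequency (%.4g cycles/nm): the projected pattern would ",
      "alias; use a finer camera sample grid"), cutoff_nm, nyq_out),
      call. = FALSE)
  }
  Fm <- fft2(mask)
  H <- otf_grid(nrow(mask), ncol(mask), d_slm, cutoff_nm)
  Fc <- fourier_resize(Fm * H, out_shape)
  illum <- Re(ifft2(Fc))
  pmin(pmax(illum, 0), 1)
}

# Convolve an image with a transfer function sampled on its FFT grid.
apply_transfer <- function(img, transfer) {
  Re(ifft2(fft2(img) * transfer))
}

defocus_sigma <- function(defocus, config, n_immersion = 1.518) {
  defocus * config$na / n_immersion
}

#' Simulate a raw SIM acquisition
#'
#' For each pattern in the repertoire: project the mask into the sample
#' plane ([project_pattern()]), multiply with the fluorophore density,
#' blur with the emission-wavelength PSF, add the defocused background
#' plane contribution (if any), scale so the noise-free widefield peak
#' equals `noise$peak_photons`, then apply Poisson shot noise and Gaussian
#' read noise.  Deterministic for a fixed `noise$seed`.
#'
#' The background plane (see [generate_two_plane_phantom()]) is blurred by
#' the emission PSF convolved with a defocus Gaussian of width
#' `sigma = defocus * NA / n` (n = 1.518, oil), and is illuminated with the
#' same Gaussian-blurred pattern, which attenuates the pattern modulation
#' by `exp(-2 pi^2 sigma^2 k^2)` -- far out of focus the pattern vanishes.
#'
#' @param phantom A [phantom()]; its `pixel` must match
#'   `sample_pixel(config)` and its shape the projected SLM grid.
#' @param seq A [build_repertoire()] pattern sequence.
#' @param config An [optical_config()].
#' @param noise A [noise_model()].
#' @return An object of class `raw_stack` with fields `frames` (list of
#'   matrices, photons), `sequence`, `config`, `noise`, `pixel`.
#' @export
simulate_acquisition <- function(phantom, seq, config, noise = noise_model()) {
  stopifnot(inherits(phantom, "phantom"), inherits(seq, "pattern_sequence"),
            inherits(config, "optical_config"), inherits(noise, "noise_model"))
  if (abs(phantom$pixel - sample_pixel(config)) > 1e-6) {
    stop("phantom pixel size does not match the camera sample pixel",
         call. = FALSE)
  }
  out_shape <- sample_grid_shape(seq$shape, config)
  if (!all(dim(phantom$density) == out_shape)) {
    stop(sprintf("phantom shape %d x %d does not match the projected SLM grid %d x %d",
                 nrow(phantom$density), ncol(phantom$density),
                 out_shape[1], out_shape[2]), call. = FALSE)
  }
  d <- phantom$pixel
  nr <- out_shape[1]
  nc <- out_shape[2]
  cutoff_em <- widefield_cutoff(config, "emission") / 1000
  H_em <- otf_grid(nr, nc, d, cutoff_em)
  if (!is.null(phantom$background)) {
    G <- gaussian_transfer(nr, nc, d, defocus_sigma(phantom$defocus, config))
    H_bg <- H_em * G
  }
  expected <- vector("list", length(seq$masks))
  for (i in seq_along(seq$masks)) {
    illum <- project_pattern(seq$masks[[i]], config)
    fr <- apply_transfer(phantom$density * illum, H_em)
    if (!is.null(phantom$background)) {
      illum_def <- apply_transfer(illum, G)
      fr <- fr + apply_transfer(phantom$background * illum_def, H_bg)
    }
    expected[[i]] <- pmax(fr, 0)
  }
  wf_peak <- max(Reduce(`+`, expected)) / length(expected)
  scale <- if (wf_peak > 0) noise$peak_photons / wf_peak else 0
  frames <- with_seed(noise$seed, {
    lapply(expected, function(e) {
      f <- e * scale
      if (noise$shot_noise) {
        f <- matrix(stats::rpois(length(f), f), nrow(f), ncol(f))
      }
      if (noise$read_sigma > 0) {
        f <- f + matrix(stats::rnorm(length(f), 0, noise$read_sigma),
                        nrow(f), ncol(f))
      }
      f
    })
  })
  structure(list(frames = frames, sequence = seq, config = config,
                 noise = noise, pixel = d),
            class = "raw_stack")
}

#' @export
print.raw_stack <- function(x, ...) {
  cat(sprintf("<raw_stack> %d frames, %d x %d px at %.1f nm/px\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel))
  invisible(x)
}

#' @export
length.raw_stack <- function(x) length(x$frames)
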