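#' Bead-field resolution experiment (widefield vs SR-SIM)
#'
#' End-to-end experiment: a field of isolated sub-diffraction beads is
#' simulated through the full incoherent-SIM forward model (SLM pattern
#' projection, emission blur, shot and read noise), reconstructed both as a
#' widefield-equivalent image and with SR-SIM, and both images are measured
#' by per-bead 2D Gaussian FWHM fits.
#'
#' All randomness (bead placement and noise) derives from `seed`; repeated
#' calls with the same arguments are bit-identical.
#'
#' @param seed Integer master seed.
#' @param n_beads Number of beads (default 20).
#' @param config An [optical_config()].
#' @param preset Pattern repertoire preset (default `"bio12"`).
#' @param slm_shape SLM region in pixels.
#' @param base_period Pattern period in SLM pixels.
#' @param peak_photons,read_sigma Noise model parameters.
#' @param params A [recon_params()].
#' @param window_widefield,window_sr Gaussian-fit window half-widths
#'   (pixels) on the widefield and SR grids.
#' @return An object of class `bead_resolution_result`: `fwhm_widefield`
#'   and `fwhm_sr` ([mean_fwhm_over_beads()] reports), `widefield`, `sr`
#'   (an `sr_result`), `positions` (nm), `pattern_frequency_ratio` (nominal
#'   pattern frequency over the excitation cutoff), `config`.
#' @export
bead_resolution_experiment <- function(seed = 1, n_beads = 20,
                                       config = optical_config(),
                                       preset = "bio12",
                                       slm_shape = c(320, 320),
                                       base_period = 4,
                                       peak_photons = 1e4, read_sigma = 2,
                                       params = recon_params(),
                                       window_widefield = 8,
                                       window_sr = 12) {
  stopifnot(n_beads >= 1, seed == round(seed))
  seq_ <- build_repertoire(preset, slm_shape, base_period)
  shape <- sample_grid_shape(seq_$shape, config)
  d <- sample_pixel(config)
  # derived sub-seeds, kept well below 2^31
  bead_seed <- (abs(seed) %% 1e9) * 2 + 1
  noise_seed <- (abs(seed) %% 1e9) * 2 + 2
  ph <- generate_bead_phantom(n_beads, shape, d, seed = bead_seed)
  stack <- simulate_acquisition(
    ph, seq_, config, noise_model(peak_photons, read_sigma, seed = noise_seed))
  wf <- widefield_from_stack(stack)
  sr <- reconstruct_sr_sim(stack, params)
  rep_wf <- mean_fwhm_over_beads(wf, ph$positions / d + 1, d,
                                 window = window_widefield)
  rep_sr <- mean_fwhm_over_beads(sr$image, ph$positions / sr$pixel + 1,
                                 sr$pixel, window = window_sr)
  k_nom <- sqrt(sum(nominal_k(seq_$specs[[1]], config)^2)) * 1000
  structure(list(fwhm_widefield = rep_wf, fwhm_sr = rep_sr,
                 widefield = wf, sr = sr, positions = ph$positions,
                 pattern_frequency_ratio =
                   k_nom / widefield_cutoff(config, "excitation"),
                 config = config),
            class = "bead_resolution_result")
}

#' @export
print.bead_resolution_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<bead_resolution_result> pattern at %.3f of excitation cutoff\n",
    "  widefield FWHM %.1f nm (n = %d)\n  SR-SIM    FWHM %.1f nm (n = %d)\n"),
    x$pattern_frequency_ratio,
    x$fwhm_widefield$mean, x$fwhm_widefield$n,
    x$fwhm_sr$mean, x$fwhm_sr$n))
  invisible(x)
}

#' Measured pattern contrast versus frequency
#'
#' Sweeps binary line patterns across normalized frequencies, projects each
#' through the excitation path, and measures the contrast transfer as the
#' ratio of output to input modulation depth (first harmonic over DC).  In
#' `"incoherent"` mode the pattern is an image of the SLM formed with
#' incoherent light and the measured transfer follows the incoherent OTF;
#' in `"coherent"` mode the pattern is an ideal interference fringe whose
#' contrast is frequency-independent.
#'
#' Requested frequencies are snapped to the common Fourier grid of the SLM
#' and camera fields of view so the harmonic can be read out without
#' spectral leakage.
#'
#' @param rhos Normalized frequencies (fraction of the excitation cutoff),
#'   in (0, 1).
#' @param config An [optical_config()].
#' @param mode `"incoherent"` or `"coherent"`.
#' @param shape SLM region in pixels.
#' @return A data.frame with columns `rho` (snapped), `frequency`
#'   (cycles/um), `measured` and `predicted` contrast transfer.
#' @export
pattern_contrast_sweep <- function(rhos, config = optical_config(),
                                   mode = c("incoherent", "coherent"),
                                   shape = c(320, 320)) {
  mode <- match.arg(mode)
  if (any(rhos <= 0 | rhos >= 1)) {
    stop("`rhos` must lie strictly inside (0, 1)", call. = FALSE)
  }
  cut_nm <- widefield_cutoff(config, "excitation") / 1000
  d_slm <- slm_sample_pixel(config)
  d_out <- sample_pixel(config)
  out_shape <- sample_grid_shape(shape, config)
  L <- shape[1] * d_slm            # field of view along rows, nm
  out <- lapply(rhos, function(rho) {
    m <- max(1, round(rho * cut_nm * L))     # harmonic index on the FOV
    k_nm <- m / L
    rho_snap <- k_nm / cut_nm
    if (mode == "incoherent") {
      period_px <- 1 / (k_nm * d_slm)
      mask <- make_line_pattern(
        pattern_spec(0, period_px, 0, 2, duty = 0.5), shape)
      proj <- project_pattern(mask, config)
      m_in <- 2 * Mod(dft_at(mask, 0, k_nm, d_slm)) / sum(mask)
      m_out <- 2 * Mod(dft_at(proj, 0, k_nm, d_out)) / sum(proj)
    } else {
      r <- (seq_len(out_shape[1]) - 1) * d_out
      fringe <- matrix(0.5 * (1 + cos(2 * pi * k_nm * r)),
                       out_shape[1], out_shape[2])
      m_in <- 1
      m_out <- 2 * Mod(dft_at(fringe, 0, k_nm, d_out)) / sum(fringe)
    }
    data.frame(rho = rho_snap, frequency = k_nm * 1000,
               measured = m_out / m_in,
               predicted = pattern_contrast_curve(rho_snap, mode))
  })
  do.call(rbind, out)
}

#' Two-point resolution experiment (widefield vs SR-SIM)
#'
#' Simulates a pair of beads at a fixed centre-to-centre separation through
#' the full forward model and applies the dip criterion ([pair_resolved()])
#' to the widefield and SR-SIM images.
#'
#' @param separation Centre-to-centre distance in nm.
#' @param seed Integer master seed (noise).
#' @param config An [optical_config()].
#' @param preset,slm_shape,base_period Repertoire settings.
#' @param peak_photons,read_sigma Noise model parameters.
#' @param dip_threshold Required relative dip (default 0.1).
#' @param params A [recon_params()].  The default uses the nominal pattern
#'   metadata: Fourier parameter estimation needs a structured field, and a
#'   two-bead sample is too sparse for a significant pattern peak.
#' @return A list: `widefield` and `sr` ([pair_resolved()] results),
#'   `widefield_image`, `sr_image`, `separation`, `positions`.
#' @export
bead_pair_experiment <- function(separation = 200, seed = 1,
                                 config = optical_config(),
                                 preset = "bio12",
                                 slm_shape = c(320, 320), base_period = 4,
                                 peak_photons = 1e4, read_sigma = 2,
                                 dip_threshold = 0.1,
                                 params = recon_params(
                                   phase_source = "metadata")) {
  seq_ <- build_repertoire(preset, slm_shape, base_period)
  shape <- sample_grid_shape(seq_$shape, config)
  d <- sample_pixel(config)
  noise_seed <- (abs(seed) %% 1e9) * 2 + 2
  ph <- generate_bead_pair(separation, shape, d)
  stack <- simulate_acquisition(
    ph, seq_, config, noise_model(peak_photons, read_sigma, seed = noise_seed))
  wf <- widefield_from_stack(stack)
  sr <- reconstruct_sr_sim(stack, params)
  p_wf <- ph$positions / d + 1
  p_sr <- ph$positions / sr$pixel + 1
  list(widefield = pair_resolved(wf, p_wf[1, ], p_wf[2, ], dip_threshold),
       sr = pair_resolved(sr$image, p_sr[1, ], p_sr[2, ], dip_threshold),
       widefield_image = wf, sr_image = sr$image,
       separation = separation, positions = ph$positions)
}

#' Optical-sectioning experiment on a two-plane phantom
#'
#' Places in-focus structure in the left half of the field and identical
#' structure in the right half on a plane `defocus` nm out of focus,
#' simulates an acquisition, and compares how much of the image energy
#' falls in the defocused half for the widefield versus the OS-SIM
#' reconstruction.  Square-law OS-SIM suppresses the unmodulated defocused
#' light, so its defocused-half energy fraction should be a small fraction
#' of the widefield one.
#'
#' @param seed Integer master seed (noise).
#' @param config An [optical_config()].
#' @param defocus Background-plane defocus in nm.
#' @param preset,slm_shape,base_period Repertoire settings.
#' @param peak_photons,read_sigma Noise model parameters; the default peak
#'   signal is high so the residual shot-noise floor of the square-law
#'   estimator stays well below the rejected background.
#'
#' @details The default repertoire is `bio12`: with duty 1/4 on a period of
#'   4 SLM pixels every phase mask is an exact lattice translate of the
#'   others, so all frames share the same mean illumination (DC).  Equal DC
#'   across phases is required by square-law detection -- a repertoire
#'   whose duty window is not representable on the pixel grid (e.g. duty
#'   1/3 of a 4-pixel period) has phase-dependent DC, which the square law
#'   reads as spurious modulation of the defocused background.
#' @return A list: `fraction_widefield`, `fraction_os` (energy fraction of
#'   the defocused half in each image), `ratio`
#'   (`fraction_os / fraction_widefield`), `widefield`, `os` (an
#'   `os_result`).
#' @export
sectioning_experiment <- function(seed = 1, config = optical_config(),
                                  defocus = 1600,
                                  preset = "bio12",
                                  slm_shape = c(320, 320), base_period = 4,
                                  peak_photons = 1e6, read_sigma = 2) {
  seq_ <- build_repertoire(preset, slm_shape, base_period)
  shape <- sample_grid_shape(seq_$shape, config)
  d <- sample_pixel(config)
  noise_seed <- (abs(seed) %% 1e9) * 2 + 2
  half <- floor(shape[2] / 2)
  # identical disk lattices, one per half-field, margin away from the split
  lattice <- function(density, cols_nm) {
    rows_nm <- seq(0.2, 0.8, by = 0.15) * (shape[1] - 1) * d
    for (r in rows_nm) for (c in cols_nm) {
      density <- rasterize_disk(density, c(r, c), 400, d)
    }
    density
  }
  cols_left <- seq(0.10, 0.35, by = 0.08) * (shape[2] - 1) * d
  cols_right <- seq(0.65, 0.90, by = 0.08) * (shape[2] - 1) * d
  focal <- lattice(matrix(0, shape[1], shape[2]), cols_left)
  backg <- lattice(matrix(0, shape[1], shape[2]), cols_right)
  ph <- generate_two_plane_phantom(focal, backg, defocus, d)
  stack <- simulate_acquisition(
    ph, seq_, config, noise_model(peak_photons, read_sigma, seed = noise_seed))
  wf <- widefield_from_stack(stack)
  os <- reconstruct_os_sim(stack)
  frac <- function(img) {
    img <- pmax(img, 0)
    sum(img[, (half + 1):shape[2]]) / sum(img)
  }
  fw <- frac(wf)
  fo <- frac(os$image)
  list(fraction_widefield = fw, fraction_os = fo, ratio = fo / fw,
       widefield = wf, os = os)
}
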