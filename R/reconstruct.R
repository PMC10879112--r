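#' Reconstruction parameters
#'
#' @param wiener_w Wiener regularization, relative to the (unit) OTF peak;
#'   `wiener_w^2` is added to the summed squared band OTFs.  Default 0.05.
#' @param apodization `"triangle"` (Lukosz window falling linearly to zero
#'   at the extended passband radius) or `"none"`.
#' @param phase_source `"estimated"` (pattern frequency and phases measured
#'   from the data; hardware phases are only nominal) or `"metadata"` (use
#'   the nominal values carried by the pattern sequence).
#' @param upsample Fourier zero-padding factor for the output grid, 1 or 2.
#'   The extended passband exceeds the native Nyquist frequency whenever
#'   the pattern frequency is appreciable, so 2 is the default.
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(wiener_w = 0.05,
                         apodization = c("triangle", "none"),
                         phase_source = c("estimated", "metadata"),
                         upsample = 2) {
  stopifnot(wiener_w > 0, upsample %in% c(1, 2))
  structure(list(wiener_w = wiener_w,
                 apodization = match.arg(apodization),
                 phase_source = match.arg(phase_source),
                 upsample = as.integer(upsample)),
            class = "recon_params")
}

#' Widefield-equivalent image from a raw pattern stack
#'
#' Pixelwise mean of all frames.  For a homogeneous repertoire (every pixel
#' illuminated equally often across the sequence) this is the image the
#' system would record under uniform illumination.
#'
#' @param stack A `raw_stack`.
#' @return A matrix.
#' @export
widefield_from_stack <- function(stack) {
  stopifnot(inherits(stack, "raw_stack"))
  if (length(stack$frames) == 0) stop("empty stack", call. = FALSE)
  Reduce(`+`, stack$frames) / length(stack$frames)
}

# Frame indices grouped by orientation, in sequence order.
angle_groups <- function(seq) {
  angles <- sequence_angles(seq)
  split(seq_along(angles), factor(angles, levels = unique(angles)))
}

# Nominal pattern frequency vector (kx, ky) in cycles/nm for one spec.
nominal_k <- function(spec, config) {
  period_nm <- spec$period * slm_sample_pixel(config)
  a <- spec$angle * pi / 180
  c(kx = sin(a) / period_nm, ky = cos(a) / period_nm)
}

# Nominal illumination phase of one pattern: first harmonic of a binary
# duty window starting at offset phase_index/n_phases of a period.
nominal_phase <- function(spec) {
  -2 * pi * (spec$phase_index / spec$n_phases + spec$duty / 2)
}

#' Estimate pattern frequency and phases from a raw stack
#'
#' For each orientation, the pattern frequency is located as the dominant
#' off-centre peak of the frames' Fourier spectra (widefield subtracted),
#' refined to sub-bin precision by a nested grid search on the exact DFT;
#' per-frame phases are the complex arguments of the DFT at the refined
#' frequency.  When the stack carries pattern metadata the search is seeded
#' at the nominal frequency, otherwise a global spectral peak search is
#' used.
#'
#' @param stack A `raw_stack`.
#' @param angle_grouping Optional list of frame-index vectors, one per
#'   orientation; defaults to the grouping given by the stack's pattern
#'   sequence.
#' @return A list with one element per orientation: `angle`, `k` (cycles/um,
#'   vector of x and y components), `k_mag` (cycles/um), `phases` (radians),
#'   `strength` (peak-to-ring power ratio) and `coherence` (fraction of the
#'   per-frame peak power locked to the nominal phase increments; `NA` when
#'   no metadata anchors are available).
#' @export
estimate_pattern_parameters <- function(stack, angle_grouping = NULL) {
  stopifnot(inherits(stack, "raw_stack"))
  if (is.null(angle_grouping)) {
    if (is.null(stack$sequence)) {
      stop("stack has no pattern metadata; supply `angle_grouping`",
           call. = FALSE)
    }
    angle_grouping <- angle_groups(stack$sequence)
  }
  if (any(lengths(angle_grouping) < 3)) {
    stop("need >= 3 frames (phases) per orientation", call. = FALSE)
  }
  wf <- widefield_from_stack(stack)
  d <- stack$pixel
  out <- vector("list", length(angle_grouping))
  for (g in seq_along(angle_grouping)) {
    idx <- angle_grouping[[g]]
    # cross-correlation images: the DFT of wf * (frame - wf) at frequency k
    # equals the Fourier-domain cross-correlation between the frame and the
    # widefield image shifted by k, which concentrates the pattern peak and
    # makes the recovered phase independent of the (random) object spectrum
    corr <- lapply(stack$frames[idx], function(f) wf * (f - wf))
    if (max(vapply(corr, function(x) max(abs(x)), numeric(1))) <=
        1e-9 * (max(abs(wf))^2 + .Machine$double.eps)) {
      stop(sprintf("orientation group %d: frames carry no pattern modulation",
                   g), call. = FALSE)
    }
    spec0 <- if (!is.null(stack$sequence)) stack$sequence$specs[[idx[1]]]
    # The SLM shifts patterns by whole sub-period steps, so the phase
    # *increments* within an orientation are digitally exact; only the
    # global phase offset and the frequency need estimating.  Anchoring the
    # correlation average to the known increments cancels the conjugate
    # band and the oblique-raster satellite terms, which would otherwise
    # bias single-frame phase estimates.
    anchor <- if (!is.null(spec0)) {
      steps <- vapply(stack$sequence$specs[idx], nominal_phase, numeric(1))
      exp(1i * (steps - steps[1]))
    }
    k0 <- if (!is.null(spec0)) nominal_k(spec0, stack$config) else
      coarse_peak(corr, d)
    fit <- refine_peak(corr, k0, d, anchor)
    strength <- peak_strength(corr, fit$k, d, anchor)
    z <- vapply(corr, function(f) dft_at(f, fit$k[1], fit$k[2], d),
                complex(1))
    if (!is.null(anchor)) {
      # two-part significance test: the peak must stand out of its
      # frequency ring AND its per-frame phases must lock to the known
      # phase increments.  An unmodulated stack can fake a moderate ring
      # ratio (the refinement maximizes over a window) or a moderate
      # coherence, but not both.
      coherence <- Mod(sum(z * Conj(anchor)))^2 /
        (length(z) * sum(Mod(z)^2))
      if (strength < 4 || coherence < 0.7) {
        stop(sprintf(paste0(
          "orientation group %d: no significant pattern peak ",
          "(peak/ring power ratio %.1f, phase coherence %.2f; need >= 4 ",
          "and >= 0.7); illumination appears unmodulated"),
          g, strength, coherence), call. = FALSE)
      }
    } else {
      coherence <- NA_real_
      if (strength < 8) {
        stop(sprintf(paste0(
          "orientation group %d: no significant pattern peak ",
          "(peak/ring power ratio %.1f < 8); illumination appears ",
          "unmodulated"), g, strength), call. = FALSE)
      }
    }
    phases <- if (!is.null(anchor)) {
      offset <- Arg(sum(z * Conj(anchor)))
      offset + Arg(anchor)
    } else {
      Arg(z)
    }
    out[[g]] <- list(
      angle = if (!is.null(spec0)) spec0$angle else NA_real_,
      k = fit$k * 1000, k_mag = sqrt(sum(fit$k^2)) * 1000,
      phases = phases, strength = strength, coherence = coherence)
  }
  out
}

# Coarse peak: argmax of the summed power spectrum outside a DC guard disk.
coarse_peak <- function(diffs, d) {
  P <- Reduce(`+`, lapply(diffs, function(f) Mod(fft2(f))^2))
  nr <- nrow(P)
  nc <- ncol(P)
  r <- freq_radius(nr, nc, d)
  guard <- 4 / (min(nr, nc) * d)
  P[r < guard] <- 0
  ij <- which(P == max(P), arr.ind = TRUE)[1, ]
  c(fft_freq(nc, d)[ij[2]], fft_freq(nr, d)[ij[1]])
}

# Correlation power at one frequency: coherent (phase-anchored) when the
# nominal phase increments are known, incoherent otherwise.
corr_power <- function(corr, kx, ky, d, anchor = NULL) {
  z <- vapply(corr, function(f) dft_at(f, kx, ky, d), complex(1))
  if (is.null(anchor)) sum(Mod(z)^2) else Mod(sum(z * Conj(anchor)))^2
}

# Nested grid search maximizing the correlation power.
refine_peak <- function(corr, k0, d, anchor = NULL) {
  n <- max(nrow(corr[[1]]), ncol(corr[[1]]))
  step <- 1 / (n * d)   # one Fourier bin
  k <- k0
  span <- step
  for (stage in 1:4) {
    grid <- expand.grid(kx = k[1] + seq(-span, span, length.out = 5),
                        ky = k[2] + seq(-span, span, length.out = 5))
    q <- vapply(seq_len(nrow(grid)), function(i) {
      corr_power(corr, grid$kx[i], grid$ky[i], d, anchor)
    }, numeric(1))
    k <- unlist(grid[which.max(q), ], use.names = FALSE)
    span <- span / 4
  }
  list(k = k)
}

# Peak significance: refined-peak correlation power over the median power
# on the ring of bins with the same |frequency|.
peak_strength <- function(corr, k, d, anchor = NULL) {
  P <- 0
  for (i in seq_along(corr)) {
    z <- fft2(corr[[i]])
    P <- P + if (is.null(anchor)) Mod(z)^2 else z * Conj(anchor[i])
  }
  P <- if (is.null(anchor)) P else Mod(P)^2
  r <- freq_radius(nrow(P), ncol(P), d)
  kmag <- sqrt(sum(k^2))
  bin <- 1 / (min(dim(P)) * d)
  ring <- P[abs(r - kmag) < bin]
  pk <- corr_power(corr, k[1], k[2], d, anchor)
  pk / (stats::median(ring) + .Machine$double.xmin)
}

#' Separate the frequency bands of one orientation
#'
#' Solves the per-pixel linear mixing model
#' `F_i = S0 + S_plus * exp(i phi_i) + S_minus * exp(-i phi_i)`
#' exactly for 3 phases and by least squares for more.  `S0` is the
#' widefield band, `S_plus`/`S_minus` carry the object spectrum shifted by
#' -/+ the pattern frequency.
#'
#' @param frames List of >= 3 matrices (one orientation).
#' @param phases Numeric vector of illumination phases (radians), pairwise
#'   distinct modulo 2 pi.
#' @return List with complex matrices `S0`, `S_plus`, `S_minus`.
#' @export
separate_bands <- function(frames, phases) {
  n <- length(frames)
  if (n < 3 || length(phases) != n) {
    stop("need >= 3 frames and one phase per frame", call. = FALSE)
  }
  A <- cbind(1, exp(1i * phases), exp(-1i * phases))
  G <- Conj(t(A)) %*% A
  if (rcond(G) < 1e-10) {
    stop("singular mixing matrix: phases are degenerate (duplicate or opposite)",
         call. = FALSE)
  }
  Fm <- vapply(frames, as.vector, numeric(length(frames[[1]])))
  rhs <- Conj(t(A)) %*% t(Fm)            # 3 x P
  Z <- solve(G, rhs)
  shape <- dim(frames[[1]])
  list(S0 = matrix(Z[1, ], shape[1], shape[2]),
       S_plus = matrix(Z[2, ], shape[1], shape[2]),
       S_minus = matrix(Z[3, ], shape[1], shape[2]))
}

# Upsample a (complex) image by Fourier zero-padding.
upsample_image <- function(img, factor) {
  if (factor == 1) return(img)
  out_shape <- dim(img) * factor
  ifft2(fourier_resize(fft2(img), out_shape))
}

#' Super-resolution SIM reconstruction (Wiener band recombination)
#'
#' Classical frequency-domain recombination: per orientation, the three
#' bands are separated ([separate_bands()]), the side bands are moved to
#' their true frequencies by phase ramps on an upsampled grid, the band
#' weights (pattern modulation depth and residual phase) are estimated from
#' the overlap with the widefield band, and all bands from all orientations
#' are combined with a generalized Wiener filter weighted by their shifted
#' OTFs, followed by apodization over the extended support.
#'
#' The effective passband radius is the pattern frequency plus the emission
#' cutoff; since a pattern can only be measured when its frequency lies
#' inside the detection passband, the radius never exceeds twice the
#' widefield emission cutoff -- the two-fold limit of linear SIM.
#'
#' @param stack A `raw_stack` covering >= 3 orientations with >= 3 phases
#'   each.
#' @param params A [recon_params()].
#' @return An object of class `sr_result`: `image` (real matrix on the
#'   upsampled grid), `pixel` (nm), `k_est` (per-orientation pattern
#'   frequency vectors, cycles/um), `phases_est`, `weights` (complex band
#'   weights), `passband_radius` (cycles/um).
#' @export
reconstruct_sr_sim <- function(stack, params = recon_params()) {
  stopifnot(inherits(stack, "raw_stack"))
  if (!inherits(params, "recon_params")) {
    stop("`params` must be a recon_params() object", call. = FALSE)
  }
  if (is.null(stack$sequence)) {
    stop("stack has no pattern metadata", call. = FALSE)
  }
  groups <- angle_groups(stack$sequence)
  if (length(groups) < 3) {
    stop("SR-SIM reconstruction needs >= 3 pattern orientations",
         call. = FALSE)
  }
  if (any(lengths(groups) < 3)) {
    stop("SR-SIM reconstruction needs >= 3 phases per orientation",
         call. = FALSE)
  }
  cfg <- stack$config
  d <- stack$pixel
  u <- params$upsample
  nr <- nrow(stack$frames[[1]])
  nc <- ncol(stack$frames[[1]])
  nr_up <- nr * u
  nc_up <- nc * u
  d_up <- d / u
  cutoff_em_nm <- widefield_cutoff(cfg, "emission") / 1000

  pars <- if (params$phase_source == "estimated") {
    estimate_pattern_parameters(stack)
  } else {
    lapply(groups, function(idx) {
      specs <- stack$sequence$specs[idx]
      k <- nominal_k(specs[[1]], cfg)
      list(angle = specs[[1]]$angle, k = k * 1000,
           k_mag = sqrt(sum(k^2)) * 1000,
           phases = vapply(specs, nominal_phase, numeric(1)),
           strength = NA_real_)
    })
  }

  k_mags_nm <- vapply(pars, function(p) p$k_mag, numeric(1)) / 1000
  if (any(k_mags_nm >= cutoff_em_nm)) {
    stop("estimated pattern frequency at or beyond the emission cutoff; pattern is not admissible",
         call. = FALSE)
  }
  passband_nm <- max(k_mags_nm) + cutoff_em_nm
  if (passband_nm > 1 / (2 * d_up)) {
    warning("extended passband exceeds the output Nyquist frequency; use upsample = 2")
  }

  O0 <- otf_grid(nr_up, nc_up, d_up, cutoff_em_nm)
  num <- matrix(0i, nr_up, nc_up)
  den <- matrix(0, nr_up, nc_up)
  x_up <- (seq_len(nc_up) - 1) * d_up
  y_up <- (seq_len(nr_up) - 1) * d_up
  weights <- vector("list", length(groups))

  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    k_nm <- pars[[g]]$k / 1000
    bands <- separate_bands(stack$frames[idx], pars[[g]]$phases)
    S0u <- upsample_image(bands$S0, u)
    Spu <- upsample_image(bands$S_plus, u)
    Smu <- upsample_image(bands$S_minus, u)
    ramp_p <- outer(exp(-2i * pi * k_nm[2] * y_up),
                    exp(-2i * pi * k_nm[1] * x_up))
    D0 <- fft2(S0u)
    Dp <- fft2(Spu * ramp_p)
    Dm <- fft2(Smu * Conj(ramp_p))
    Op <- otf_grid(nr_up, nc_up, d_up, cutoff_em_nm,
                   kx = k_nm[1], ky = k_nm[2])
    Om <- otf_grid(nr_up, nc_up, d_up, cutoff_em_nm,
                   kx = -k_nm[1], ky = -k_nm[2])
    cp <- band_weight(D0, O0, Dp, Op)
    cm <- band_weight(D0, O0, Dm, Om)
    num <- num + Conj(O0) * D0 + Conj(cp) * Op * Dp + Conj(cm) * Om * Dm
    den <- den + O0^2 + Mod(cp)^2 * Op^2 + Mod(cm)^2 * Om^2
    weights[[g]] <- c(plus = cp, minus = cm)
  }

  rho <- num / (den + params$wiener_w^2)
  nu <- freq_radius(nr_up, nc_up, d_up)
  apod <- switch(params$apodization,
                 triangle = pmax(0, 1 - nu / passband_nm),
                 none = 1)
  img <- Re(ifft2(rho * apod))
  structure(list(image = img, pixel = d_up,
                 k_est = lapply(pars, `[[`, "k"),
                 phases_est = lapply(pars, `[[`, "phases"),
                 weights = weights,
                 passband_radius = passband_nm * 1000,
                 params = params),
            class = "sr_result")
}

# Complex band weight (modulation depth and residual global phase) by
# regressing the shifted band against the widefield band in their overlap.
band_weight <- function(D0, O0, Db, Ob) {
  mask <- O0 > 0.25 & Ob > 0.25
  if (!any(mask)) return(0 + 0i)
  pred <- (D0[mask] / O0[mask]) * Ob[mask]
  denom <- sum(Mod(pred)^2)
  if (denom == 0) return(0 + 0i)
  sum(Conj(pred) * Db[mask]) / denom
}

#' @export
print.sr_result <- function(x, ...) {
  cat(sprintf("<sr_result> %d x %d px at %.2f nm/px\n",
              nrow(x$image), ncol(x$image), x$pixel))
  cat(sprintf("  passband radius %.2f cycles/um\n", x$passband_radius))
  for (g in seq_along(x$k_est)) {
    cat(sprintf("  orientation %d: |k| = %.3f cycles/um\n",
                g, sqrt(sum(x$k_est[[g]]^2))))
  }
  invisible(x)
}

#' Optically sectioned reconstruction (square-law OS-SIM)
#'
#' Square-law detection of the pattern modulation: the root of the mean
#' squared pairwise frame difference, pooled over all phase pairs of all
#' orientations.  Unmodulated (out-of-focus) light is identical in all
#' phases and cancels in the differences; in-focus structure retains the
#' pattern and survives.  Normalizing by the pair count makes the amplitude
#' independent of the number of phases.
#'
#' Shot and read noise do not cancel in frame differences: under Poisson
#' statistics `E[(F_i - F_j)^2] = (mu_i - mu_j)^2 + mu_i + mu_j +
#' 2 sigma_read^2`, so the raw square law has a noise floor proportional to
#' the local intensity -- bright defocused regions would leak into the
#' sectioned image.  With `bias_correction = TRUE` (default) the expected
#' noise term is subtracted per pair before pooling, using the read-noise
#' value carried in the stack metadata, and the pooled sum is clamped at
#' zero before the square root.  The correction is skipped automatically
#' for noise-free stacks (metadata records `shot_noise = FALSE`).
#'
#' @param stack A `raw_stack` with >= 3 phases per orientation.
#' @param bias_correction Subtract the shot/read-noise expectation from the
#'   squared differences (default `TRUE`).
#' @return An object of class `os_result` with fields `image` (non-negative
#'   matrix), `method`, `pixel`.
#' @export
reconstruct_os_sim <- function(stack, bias_correction = TRUE) {
  stopifnot(inherits(stack, "raw_stack"))
  if (is.null(stack$sequence)) {
    stop("stack has no pattern metadata", call. = FALSE)
  }
  groups <- angle_groups(stack$sequence)
  if (any(lengths(groups) < 3)) {
    stop("OS-SIM square-law detection needs >= 3 phases per orientation",
         call. = FALSE)
  }
  correct <- isTRUE(bias_correction) && !is.null(stack$noise) &&
    isTRUE(stack$noise$shot_noise)
  read_var <- if (!is.null(stack$noise)) stack$noise$read_sigma^2 else 0
  ss <- 0
  n_pairs <- 0
  for (idx in groups) {
    fr <- stack$frames[idx]
    n <- length(fr)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d2 <- (fr[[i]] - fr[[j]])^2
        if (correct) {
          d2 <- d2 - pmax(fr[[i]], 0) - pmax(fr[[j]], 0) - 2 * read_var
        }
        ss <- ss + d2
        n_pairs <- n_pairs + 1
      }
    }
  }
  structure(list(image = sqrt(pmax(ss, 0) / n_pairs),
                 method = if (correct) "square-law (noise-bias corrected)"
                          else "square-law",
                 pixel = stack$pixel),
            class = "os_result")
}

#' @export
print.os_result <- function(x, ...) {
  cat(sprintf("<os_result> %s, %d x %d px at %.1f nm/px\n", x$method,
              nrow(x$image), ncol(x$image), x$pixel))
  invisible(x)
}
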