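#' Fit an isotropic 2D Gaussian and report its FWHM
#'
#' Least-squares fit of `offset + A * exp(-((x-x0)^2+(y-y0)^2)/(2 sigma^2))`
#' to a window around a bead, via Levenberg-Marquardt.  The FWHM is
#' `2 sqrt(2 ln 2) * sigma * pixel`.  Note that a bead of finite diameter
#' inflates the fitted FWHM slightly above the true PSF FWHM; values are
#' reported raw, without bead-size deconvolution.
#'
#' @param image Matrix.
#' @param center_guess `c(row, col)` in pixels (1-based, may be fractional).
#' @param pixel Pixel size in nm.
#' @param window Half-width of the square fit window in pixels.
#' @return FWHM in nm.
#' @export
fit_gaussian_fwhm <- function(image, center_guess, pixel, window = 8) {
  r0 <- round(center_guess[1])
  c0 <- round(center_guess[2])
  rr <- max(1, r0 - window):min(nrow(image), r0 + window)
  cc <- max(1, c0 - window):min(ncol(image), c0 + window)
  sub <- image[rr, cc]
  if (max(sub) - min(sub) <= .Machine$double.eps * (abs(max(sub)) + 1)) {
    stop("flat window: no peak to fit", call. = FALSE)
  }
  df <- data.frame(
    z = as.vector(sub),
    y = rep(rr, times = length(cc)),
    x = rep(cc, each = length(rr))
  )
  # centroid of the background-subtracted window as the starting centre
  w <- pmax(df$z - min(df$z), 0)
  start <- list(
    A = max(df$z) - min(df$z),
    x0 = sum(df$x * w) / sum(w),
    y0 = sum(df$y * w) / sum(w),
    sigma = window / 3,
    b = min(df$z)
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2)),
      data = df, start = start,
      lower = c(A = 0, x0 = min(cc), y0 = min(rr), sigma = 0.25, b = -Inf),
      upper = c(A = Inf, x0 = max(cc), y0 = max(rr), sigma = 4 * window,
                b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  p <- stats::coef(fit)
  if (p[["sigma"]] <= 0.26 || p[["sigma"]] >= 3.9 * window ||
      p[["A"]] <= 0) {
    stop("Gaussian fit hit parameter bounds; window does not contain a single resolvable peak",
         call. = FALSE)
  }
  2 * sqrt(2 * log(2)) * p[["sigma"]] * pixel
}

#' FWHM statistics over a set of beads
#'
#' Fits each bead with [fit_gaussian_fwhm()]; beads whose fit fails are
#' excluded and listed in the report.
#'
#' @param image Matrix.
#' @param positions n x 2 matrix of bead centres in pixels (row, col).
#' @param pixel Pixel size in nm.
#' @param window Fit window half-width in pixels.
#' @return An object of class `fwhm_report`: `per_bead` (nm), `mean`, `sd`,
#'   `n`, `excluded` (indices of failed fits).
#' @export
mean_fwhm_over_beads <- function(image, positions, pixel, window = 8) {
  positions <- rbind(positions)
  if (nrow(positions) < 1) stop("need at least one bead position",
                                call. = FALSE)
  vals <- numeric(0)
  excluded <- integer(0)
  for (i in seq_len(nrow(positions))) {
    f <- tryCatch(fit_gaussian_fwhm(image, positions[i, ], pixel, window),
                  error = function(e) NA_real_)
    if (is.na(f)) excluded <- c(excluded, i) else vals <- c(vals, f)
  }
  if (length(vals) == 0) stop("all bead fits failed", call. = FALSE)
  structure(list(per_bead = vals, mean = mean(vals),
                 sd = if (length(vals) > 1) stats::sd(vals) else 0,
                 n = length(vals), excluded = excluded),
            class = "fwhm_report")
}

#' @export
print.fwhm_report <- function(x, ...) {
  cat(sprintf("<fwhm_report> mean %.1f nm (sd %.1f, n = %d",
              x$mean, x$sd, x$n))
  if (length(x$excluded)) cat(sprintf(", %d excluded", length(x$excluded)))
  cat(")\n")
  invisible(x)
}

# Bilinear interpolation of `image` at fractional (row, col) positions.
bilinear <- function(image, r, c) {
  r <- pmin(pmax(r, 1), nrow(image))
  c <- pmin(pmax(c, 1), ncol(image))
  r0 <- pmin(floor(r), nrow(image) - 1)
  c0 <- pmin(floor(c), ncol(image) - 1)
  fr <- r - r0
  fc <- c - c0
  image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    image[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    image[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    image[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Two-point resolvability along the inter-centre axis
#'
#' Extracts the intensity profile along the line through the two centres
#' (extended by 40% on each side) and applies a Rayleigh-like dip
#' criterion: the pair is resolved iff the profile has two local maxima
#' with an intervening minimum at least `dip_threshold` (default 10%)
#' below the lower maximum.
#'
#' @param image Matrix.
#' @param center1,center2 `c(row, col)` pixel positions of the two peaks.
#' @param dip_threshold Required relative dip depth (default 0.1).
#' @param n_samples Profile sampling density.
#' @return List with `resolved` (logical), `dip` (relative depth, 0 if no
#'   double peak) and `profile`.
#' @export
pair_resolved <- function(image, center1, center2, dip_threshold = 0.1,
                          n_samples = 201) {
  if (sqrt(sum((center1 - center2)^2)) < .Machine$double.eps) {
    stop("the two centres coincide", call. = FALSE)
  }
  t <- seq(-0.4, 1.4, length.out = n_samples)
  r <- center1[1] + t * (center2[1] - center1[1])
  c <- center1[2] + t * (center2[2] - center1[2])
  prof <- bilinear(image, r, c)
  n <- length(prof)
  is_max <- c(FALSE, prof[2:(n - 1)] > prof[1:(n - 2)] &
                prof[2:(n - 1)] >= prof[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) {
    return(list(resolved = FALSE, dip = 0, profile = prof))
  }
  ord <- order(prof[peaks], decreasing = TRUE)
  p1 <- peaks[ord[1]]
  p2 <- peaks[ord[2]]
  lo <- min(p1, p2)
  hi <- max(p1, p2)
  vmin <- min(prof[lo:hi])
  dip <- 1 - vmin / min(prof[p1], prof[p2])
  list(resolved = dip >= dip_threshold, dip = dip, profile = prof)
}

#' Radial spectral support of an image
#'
#' Azimuthally averaged log power spectrum; the support is the largest
#' radius at which the average exceeds a percentile-defined noise floor by
#' a fixed margin.  A band-limited image yields (close to) its OTF cutoff;
#' a super-resolved image of the same scene yields a larger support; white
#' noise, having no band limit, yields the Nyquist radius.
#'
#' @param image Matrix, at least 64 x 64.
#' @param pixel Pixel size in nm.
#' @param noise_floor_percentile Percentile (0-1) of all off-DC log-power
#'   bins used as the floor (default 0.1).
#' @param margin Required excess over the floor in log10 power units
#'   (default 0.5, i.e. about 3x in power).
#' @return Support radius in cycles/um.
#' @export
radial_spectrum_support <- function(image, pixel,
                                    noise_floor_percentile = 0.1,
                                    margin = 0.5) {
  if (any(dim(image) < 64)) stop("image must be at least 64 x 64",
                                 call. = FALSE)
  if (stats::sd(image) == 0) stop("constant image has no spectral support",
                                  call. = FALSE)
  P <- Mod(fft2(image - mean(image)))^2
  lp <- log10(P + .Machine$double.xmin)
  r <- freq_radius(nrow(P), ncol(P), pixel)
  nyq <- 1 / (2 * pixel)
  bin <- 1 / (max(dim(P)) * pixel)
  edges <- seq(0, nyq, by = bin)
  idx <- findInterval(r, edges)
  ok <- r > 0 & r <= nyq
  prof <- tapply(lp[ok], idx[ok], mean)
  radii <- (as.numeric(names(prof)) - 0.5) * bin
  floor_val <- stats::quantile(lp[ok], noise_floor_percentile, names = FALSE)
  above <- prof >= floor_val + margin
  if (!any(above)) return(0)
  max(radii[above]) * 1000
}

#' Maximum intensity projection
#'
#' Pixelwise maximum over a list of planes (or a 3D array along its third
#' dimension).
#'
#' @param planes List of matrices, or a 3D array.
#' @return A matrix.
#' @export
max_intensity_projection <- function(planes) {
  if (is.array(planes) && length(dim(planes)) == 3) {
    planes <- lapply(seq_len(dim(planes)[3]), function(i) planes[, , i])
  }
  if (length(planes) == 0) stop("no planes to project", call. = FALSE)
  Reduce(pmax, planes)
}
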