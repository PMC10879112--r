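#' Fluorophore phantom
#'
#' A 2D fluorophore density map on the sample-plane pixel grid, with an
#' optional defocused background plane used for optical-sectioning tests.
#' Density is in expected photons per pixel at unit illumination (relative
#' units; the acquisition noise model sets the absolute photon scale).
#'
#' @param density Non-negative matrix.
#' @param pixel Sample-plane pixel size in nm.
#' @param background Optional non-negative matrix (same shape) located
#'   `defocus` nm out of the focal plane.
#' @param defocus Defocus distance of the background plane in nm (> 0 when
#'   `background` is given).
#' @param positions Optional n x 2 matrix of object centres in nm (row
#'   coordinate, column coordinate), carried along for metrology.
#' @return An object of class `phantom`.
#' @export
phantom <- function(density, pixel, background = NULL, defocus = NULL,
                    positions = NULL) {
  stopifnot(is.matrix(density), pixel > 0)
  if (any(density < 0)) stop("`density` must be >= 0", call. = FALSE)
  if (!is.null(background)) {
    if (!all(dim(background) == dim(density))) {
      stop("`background` must match the focal-plane shape", call. = FALSE)
    }
    if (is.null(defocus) || defocus <= 0) {
      stop("a background plane requires `defocus` > 0; use a single-plane phantom for defocus = 0",
           call. = FALSE)
    }
  }
  structure(list(density = density, pixel = pixel, background = background,
                 defocus = defocus, positions = positions),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px at %.1f nm/px",
              nrow(x$density), ncol(x$density), x$pixel))
  if (!is.null(x$background)) {
    cat(sprintf(", background plane at %g nm defocus", x$defocus))
  }
  cat("\n")
  invisible(x)
}

# Rasterize a uniform disk: pixel centres within diameter/2 of (r0, c0) nm.
rasterize_disk <- function(density, center_nm, diameter, pixel) {
  half <- diameter / 2
  rr <- floor((center_nm[1] - half) / pixel):ceiling((center_nm[1] + half) / pixel)
  cc <- floor((center_nm[2] - half) / pixel):ceiling((center_nm[2] + half) / pixel)
  rr <- rr[rr >= 0 & rr < nrow(density)]
  cc <- cc[cc >= 0 & cc < ncol(density)]
  for (r in rr) {
    for (c in cc) {
      if ((r * pixel - center_nm[1])^2 + (c * pixel - center_nm[2])^2 <= half^2 ||
          # guarantee at least the nearest pixel centre lights up for
          # sub-pixel beads
          (abs(r * pixel - center_nm[1]) <= pixel / 2 &&
           abs(c * pixel - center_nm[2]) <= pixel / 2 && diameter < pixel)) {
        density[r + 1, c + 1] <- 1
      }
    }
  }
  density
}

#' Random field of isolated sub-diffraction beads
#'
#' Uniform-intensity disks of the given diameter at rejection-sampled
#' positions with a minimum pairwise centre distance, emulating a field of
#' isolated 100 nm fluorescent beads used for PSF metrology.
#'
#' @param n_beads Number of beads (>= 0).
#' @param shape Grid shape `c(rows, cols)` in pixels.
#' @param pixel Pixel size in nm.
#' @param bead_diameter Bead diameter in nm (default 100).
#' @param min_separation Minimum centre-to-centre distance in nm; must
#'   exceed the bead diameter.
#' @param margin Border margin in nm kept free of bead centres (default
#'   `min_separation`).
#' @param seed RNG seed for the rejection sampler.
#' @param max_attempts Attempts per bead before giving up.
#' @return A [phantom()] with bead centre `positions` (nm) attached.
#' @export
generate_bead_phantom <- function(n_beads, shape, pixel,
                                  bead_diameter = 100,
                                  min_separation = 2000,
                                  margin = min_separation,
                                  seed = 1, max_attempts = 5000) {
  stopifnot(n_beads >= 0, min_separation > bead_diameter)
  density <- matrix(0, shape[1], shape[2])
  if (n_beads == 0) return(phantom(density, pixel,
                                   positions = matrix(0, 0, 2)))
  fov <- (shape - 1) * pixel
  if (any(fov - 2 * margin <= 0)) {
    stop("field too small for the requested margin", call. = FALSE)
  }
  pos <- with_seed(seed, {
    pts <- matrix(NA_real_, n_beads, 2)
    placed <- 0
    attempts <- 0
    while (placed < n_beads) {
      attempts <- attempts + 1
      if (attempts > max_attempts) {
        stop(sprintf("could not place %d beads at min separation %g nm after %d attempts",
                     n_beads, min_separation, max_attempts), call. = FALSE)
      }
      cand <- c(runif(1, margin, fov[1] - margin),
                runif(1, margin, fov[2] - margin))
      ok <- placed == 0 ||
        min(sqrt((pts[seq_len(placed), 1] - cand[1])^2 +
                 (pts[seq_len(placed), 2] - cand[2])^2)) >= min_separation
      if (ok) {
        placed <- placed + 1
        pts[placed, ] <- cand
      }
    }
    pts
  })
  for (i in seq_len(n_beads)) {
    density <- rasterize_disk(density, pos[i, ], bead_diameter, pixel)
  }
  phantom(density, pixel, positions = pos)
}

#' Two beads at a controlled separation
#'
#' Places two identical beads symmetrically about the field centre along
#' the column (x) axis, for resolution (two-point) tests.
#'
#' @param separation Centre-to-centre distance in nm (> pixel).
#' @param shape Grid shape in pixels.
#' @param pixel Pixel size in nm.
#' @param bead_diameter Bead diameter in nm (default 100).
#' @return A [phantom()] with the two centres attached as `positions`.
#' @export
generate_bead_pair <- function(separation, shape, pixel,
                               bead_diameter = 100) {
  if (separation <= 0) stop("`separation` must be > 0", call. = FALSE)
  if (separation < pixel) {
    stop("`separation` below one pixel cannot be represented", call. = FALSE)
  }
  density <- matrix(0, shape[1], shape[2])
  ctr <- (shape - 1) / 2 * pixel
  p1 <- c(ctr[1], ctr[2] - separation / 2)
  p2 <- c(ctr[1], ctr[2] + separation / 2)
  density <- rasterize_disk(density, p1, bead_diameter, pixel)
  density <- rasterize_disk(density, p2, bead_diameter, pixel)
  phantom(density, pixel, positions = rbind(p1, p2))
}

#' Two-plane phantom for optical-sectioning tests
#'
#' Combines an in-focus structure with a second structure a fixed distance
#' out of focus.  During simulation the background plane is blurred by a
#' defocused PSF and sees a defocus-attenuated illumination pattern, so it
#' contributes (nearly) unmodulated light -- exactly the component that
#' square-law OS-SIM is designed to reject.
#'
#' @param focal_map In-focus density matrix.
#' @param background_map Out-of-focus density matrix (same shape).
#' @param defocus Defocus distance in nm (> 0).
#' @param pixel Pixel size in nm.
#' @return A [phantom()].
#' @export
generate_two_plane_phantom <- function(focal_map, background_map, defocus,
                                       pixel) {
  phantom(focal_map, pixel, background = background_map, defocus = defocus)
}
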