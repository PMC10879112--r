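#' Specification of one binary line pattern
#'
#' Describes a single periodic line pattern on the SLM pixel grid: its
#' orientation, period (in SLM pixels; possibly non-integer for diagonal
#' lattice directions), phase index within the per-orientation phase cycle,
#' and duty (on-fraction per period).
#'
#' @param angle Orientation in degrees.  `angle = 0` gives horizontal lines
#'   (intensity varying along rows), `angle = 90` vertical lines.
#' @param period Line period in SLM pixels, `>= 2`.
#' @param phase_index Integer in `[0, n_phases)`; the pattern is shifted
#'   along its normal by `phase_index / n_phases` of a period.
#' @param n_phases Number of phase steps per orientation (>= 1).
#' @param duty On-fraction per period, in (0, 1).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(angle, period, phase_index = 0, n_phases = 3,
                         duty = 1 / n_phases) {
  if (period < 2) {
    stop("`period` below 2 SLM pixels is not representable on the binary pixel grid",
         call. = FALSE)
  }
  if (!(duty > 0 && duty < 1)) stop("`duty` must be in (0, 1)", call. = FALSE)
  if (n_phases < 1 || phase_index < 0 || phase_index >= n_phases) {
    stop("`phase_index` must lie in [0, n_phases)", call. = FALSE)
  }
  structure(list(angle = angle, period = period,
                 phase_index = phase_index, n_phases = n_phases,
                 duty = duty),
            class = "pattern_spec")
}

#' Rasterize a binary line pattern on the SLM grid
#'
#' A pixel is switched on if and only if its centre falls inside the duty
#' window of the shifted periodic pattern (no anti-aliasing -- LCOS pixels
#' are strictly binary).  With 0-based pixel coordinates `(r, c)`, the
#' position along the pattern normal is `u = c sin(a) + r cos(a)` and the
#' pixel is on iff `frac(u / period - phase_index / n_phases) < duty`.
#'
#' @param spec A [pattern_spec()].
#' @param shape Integer `c(rows, cols)`, at least 8 x 8.
#' @return An integer matrix of 0/1 values.
#' @examples
#' m <- make_line_pattern(pattern_spec(0, 4, 0, 4, duty = 0.5), c(8, 8))
#' rowSums(m)  # rows 1,2,5,6 fully on
#' @export
make_line_pattern <- function(spec, shape) {
  stopifnot(inherits(spec, "pattern_spec"), length(shape) == 2)
  if (any(shape < 8)) stop("`shape` must be at least 8 x 8", call. = FALSE)
  a <- spec$angle * pi / 180
  r <- seq_len(shape[1]) - 1
  cc <- seq_len(shape[2]) - 1
  u <- outer(r * cos(a), rep(1, shape[2])) +
    outer(rep(1, shape[1]), cc * sin(a))
  t <- (u / spec$period - spec$phase_index / spec$n_phases) %% 1
  # snap float noise at the window boundaries so that, for duty = 1/n with
  # n phase steps, the per-orientation windows still partition the period
  # exactly (every pixel on in exactly one phase)
  eps <- 1e-9
  t[t >= 1 - eps] <- t[t >= 1 - eps] - 1
  mask <- matrix(0L, shape[1], shape[2])
  mask[t < spec$duty - eps] <- 1L
  mask
}

#' Mark-to-area ratio of a binary mask
#'
#' Fraction of SLM pixels switched on.  Matching this across orientations
#' keeps the illumination dose per orientation uniform.
#'
#' @param mask Binary (0/1) matrix.
#' @return Fraction in `[0, 1]`.
#' @export
mark_to_area_ratio <- function(mask) {
  if (!all(mask %in% c(0, 1))) {
    stop("`mask` must be strictly binary (0/1)", call. = FALSE)
  }
  mean(mask)
}

# Lattice-representable period along a diagonal: pixel centres project onto
# the 45-degree normal in steps of sqrt(2)/2 px, so periods must be
# m * sqrt(2)/2 for integer m; pick m nearest to the requested period.
diagonal_period <- function(base_period) {
  m <- max(3L, round(base_period * sqrt(2)))
  m / sqrt(2)
}

#' Build a pattern repertoire
#'
#' Generates the ordered pattern sequence (angle-major, phase-minor) for one
#' of three presets:
#' \describe{
#'   \item{minimal9}{orientations 0/60/120 degrees, 3 phases each spaced by
#'     120 degrees (duty 1/3) -- the minimal set for nearly isotropic 2D
#'     linear SIM.}
#'   \item{bio12}{orientations 0/60/120 degrees, 4 phases each (duty 1/4);
#'     the extra phase adds redundancy for live samples.}
#'   \item{fixed14}{orientations 0/45/90/135 degrees with 4+3+4+3 phases;
#'     the diagonal orientations use the nearest lattice-representable
#'     period so their sample-plane frequency stays close to the
#'     axis-aligned one.}
#' }
#' Within each orientation, the phase step is `period / n_phases` and
#' `duty = 1 / n_phases`, so the per-orientation phase sum covers every
#' pixel exactly once: the summed illumination is homogeneous and the mean
#' mark-to-area ratio per orientation is exactly `duty`.
#'
#' @param preset `"minimal9"`, `"bio12"` or `"fixed14"`.
#' @param shape SLM region in pixels, `c(rows, cols)`.
#' @param base_period Line period for the axis-aligned orientations, in SLM
#'   pixels (default 4).
#' @return An object of class `pattern_sequence`: fields `masks` (list of
#'   binary matrices), `specs` (list of [pattern_spec()]), `shape`,
#'   `preset`, `base_period`.
#' @export
build_repertoire <- function(preset = c("minimal9", "bio12", "fixed14"),
                             shape = c(320, 320), base_period = 4) {
  preset <- match.arg(preset)
  plan <- switch(preset,
    minimal9 = data.frame(angle = c(0, 60, 120), n_phases = 3,
                          period = base_period),
    bio12 = data.frame(angle = c(0, 60, 120), n_phases = 4,
                       period = base_period),
    fixed14 = data.frame(angle = c(0, 45, 90, 135),
                         n_phases = c(4, 3, 4, 3),
                         period = c(base_period, diagonal_period(base_period),
                                    base_period, diagonal_period(base_period)))
  )
  specs <- list()
  masks <- list()
  for (i in seq_len(nrow(plan))) {
    for (p in seq_len(plan$n_phases[i]) - 1) {
      sp <- pattern_spec(plan$angle[i], plan$period[i], p, plan$n_phases[i])
      specs[[length(specs) + 1]] <- sp
      masks[[length(masks) + 1]] <- make_line_pattern(sp, shape)
    }
  }
  structure(list(masks = masks, specs = specs, shape = as.integer(shape),
                 preset = preset, base_period = base_period),
            class = "pattern_sequence")
}

#' @export
print.pattern_sequence <- function(x, ...) {
  angles <- vapply(x$specs, `[[`, numeric(1), "angle")
  cat(sprintf("<pattern_sequence> %d masks (%s), %d x %d SLM px\n",
              length(x$masks), if (is.null(x$preset)) "custom" else x$preset,
              x$shape[1], x$shape[2]))
  cat("  orientations:", paste(unique(angles), collapse = ", "), "deg\n")
  invisible(x)
}

#' @export
length.pattern_sequence <- function(x) length(x$masks)

sequence_angles <- function(seq) {
  vapply(seq$specs, `[[`, numeric(1), "angle")
}

#' Homogeneity of the summed illumination
#'
#' Maximum relative deviation of the per-pixel sum of all masks from its
#' spatial mean.  0 means the repertoire tiles the field perfectly (every
#' pixel is illuminated equally often over the sequence).
#'
#' @param seq A [build_repertoire()] sequence.
#' @param border Number of border pixels to exclude (default 0).
#' @return Non-negative scalar.
#' @export
homogeneity_residual <- function(seq, border = 0) {
  stopifnot(inherits(seq, "pattern_sequence"))
  if (length(seq$masks) == 0) stop("empty sequence", call. = FALSE)
  S <- Reduce(`+`, seq$masks)
  if (border > 0) {
    S <- S[(border + 1):(nrow(S) - border), (border + 1):(ncol(S) - border)]
  }
  m <- mean(S)
  if (m == 0) stop("all-off sequence has undefined homogeneity", call. = FALSE)
  max(abs(S - m)) / m
}

#' Mark-to-area uniformity across orientations
#'
#' Maximum pairwise difference of the mean mark-to-area ratio between
#' orientations.
#'
#' @param seq A [build_repertoire()] sequence with at least two orientations.
#' @return Non-negative scalar.
#' @export
mar_uniformity <- function(seq) {
  stopifnot(inherits(seq, "pattern_sequence"))
  angles <- sequence_angles(seq)
  if (length(unique(angles)) < 2) {
    stop("MAR uniformity needs at least two orientations", call. = FALSE)
  }
  mars <- vapply(seq$masks, mark_to_area_ratio, numeric(1))
  per_angle <- tapply(mars, angles, mean)
  max(dist(per_angle))
}

#' Write / read a pattern repertoire as multi-page TIFF plus sidecar
#'
#' One 8-bit page per mask (values 0/255) and a plain-text YAML sidecar
#' (same path, `.yml` extension) recording shape, preset and the per-page
#' angle/period/phase/duty.  `read_repertoire()` reverses the export
#' bit-exactly.
#'
#' @param seq A `pattern_sequence`.
#' @param path Output TIFF path.
#' @return `write_repertoire()` returns `path` invisibly;
#'   `read_repertoire()` returns a `pattern_sequence`.
#' @export
write_repertoire <- function(seq, path) {
  stopifnot(inherits(seq, "pattern_sequence"))
  pages <- lapply(seq$masks, function(m) m * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none",
                  reduce = FALSE)
  sidecar <- list(
    schema_version = 1L,
    kind = "pattern_repertoire",
    shape = as.integer(seq$shape),
    preset = seq$preset,
    base_period = seq$base_period,
    patterns = lapply(seq$specs, function(s) {
      list(angle = s$angle, period = s$period, phase_index = s$phase_index,
           n_phases = s$n_phases, duty = s$duty)
    })
  )
  yaml::write_yaml(sidecar, sidecar_path(path))
  invisible(path)
}

#' @rdname write_repertoire
#' @export
read_repertoire <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(sidecar_path(path))
  if (length(pages) != length(meta$patterns)) {
    stop("TIFF page count does not match sidecar pattern list", call. = FALSE)
  }
  masks <- lapply(pages, function(p) {
    m <- matrix(as.integer(round(p)), nrow(p), ncol(p))
    m
  })
  specs <- lapply(meta$patterns, function(s) {
    pattern_spec(s$angle, s$period, s$phase_index, s$n_phases, s$duty)
  })
  structure(list(masks = masks, specs = specs,
                 shape = as.integer(meta$shape),
                 preset = meta$preset, base_period = meta$base_period),
            class = "pattern_sequence")
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yml")
}
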