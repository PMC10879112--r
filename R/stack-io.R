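#' Write / read a raw acquisition stack as multi-page TIFF plus sidecar
#'
#' Frames are stored as 32-bit float TIFF pages, in the exact order of the
#' pattern sequence, linearly mapped to `[0, 1]` with the offset and scale
#' recorded in the YAML sidecar (same path, `.yml` extension).  The sidecar
#' also carries the full acquisition provenance: schema version, optical
#' configuration, pattern sequence (preset and parameters -- masks are
#' regenerated deterministically on read), and noise model including the
#' seed.  Unknown sidecar keys are preserved on read.
#'
#' @param stack A `raw_stack`.
#' @param path Output TIFF path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   a `raw_stack`.  A TIFF without sidecar is read as a bare stack (frames
#'   only) with a warning.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "raw_stack"))
  lo <- min(vapply(stack$frames, min, numeric(1)), 0)
  hi <- max(vapply(stack$frames, max, numeric(1)))
  scale <- max(hi - lo, .Machine$double.eps)
  pages <- lapply(stack$frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  seq_ <- stack$sequence
  sidecar <- list(
    schema_version = 1L,
    kind = "raw_stack",
    n_frames = length(stack$frames),
    value_offset = lo,
    value_scale = scale,
    pixel_nm = stack$pixel,
    config = unclass(stack$config),
    noise = if (!is.null(stack$noise)) unclass(stack$noise),
    sequence = if (!is.null(seq_)) list(
      shape = as.integer(seq_$shape),
      preset = seq_$preset,
      base_period = seq_$base_period,
      patterns = lapply(seq_$specs, function(s) {
        list(angle = s$angle, period = s$period,
             phase_index = s$phase_index, n_phases = s$n_phases,
             duty = s$duty)
      })
    )
  )
  yaml::write_yaml(sidecar, sidecar_path(path))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p
  })
  scpath <- sidecar_path(path)
  if (!file.exists(scpath)) {
    warning("no sidecar found; reading as bare stack without metadata")
    return(structure(list(frames = pages, sequence = NULL, config = NULL,
                          noise = NULL, pixel = NA_real_),
                     class = "raw_stack"))
  }
  meta <- yaml::read_yaml(scpath)
  if (!is.null(meta$n_frames) && meta$n_frames != length(pages)) {
    stop(sprintf("sidecar records %d frames but TIFF has %d pages",
                 meta$n_frames, length(pages)), call. = FALSE)
  }
  frames <- lapply(pages, function(p) p * meta$value_scale + meta$value_offset)
  cfg <- NULL
  if (!is.null(meta$config)) {
    cfg <- do.call(optical_config, meta$config)
  }
  seq_ <- NULL
  if (!is.null(meta$sequence)) {
    specs <- lapply(meta$sequence$patterns, function(s) {
      pattern_spec(s$angle, s$period, s$phase_index, s$n_phases, s$duty)
    })
    shape <- as.integer(meta$sequence$shape)
    masks <- lapply(specs, make_line_pattern, shape = shape)
    seq_ <- structure(list(masks = masks, specs = specs, shape = shape,
                           preset = meta$sequence$preset,
                           base_period = meta$sequence$base_period),
                      class = "pattern_sequence")
  }
  noise <- NULL
  if (!is.null(meta$noise)) {
    noise <- do.call(noise_model, meta$noise)
  }
  structure(list(frames = frames, sequence = seq_, config = cfg,
                 noise = noise, pixel = meta$pixel_nm, extra_meta = meta),
            class = "raw_stack")
}

#' Write reconstruction results as TIFF images plus a sidecar report
#'
#' Writes widefield, OS-SIM and SR-SIM images (each a single-page 32-bit
#' float TIFF, scaled as in [write_stack()]) and a YAML report with the
#' estimated pattern frequencies, phases, passband and reconstruction
#' parameters.
#'
#' @param widefield,os,sr Widefield matrix, `os_result`, `sr_result` (any
#'   may be `NULL`).
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(prefix, widefield = NULL, os = NULL, sr = NULL) {
  written <- character(0)
  save_img <- function(img, suffix) {
    p <- paste0(prefix, "_", suffix, ".tif")
    lo <- min(img, 0)
    scale <- max(max(img) - lo, .Machine$double.eps)
    tiff::writeTIFF((img - lo) / scale, p, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(widefield)) save_img(widefield, "widefield")
  if (!is.null(os)) save_img(os$image, "os")
  if (!is.null(sr)) save_img(sr$image, "sr")
  if (!is.null(sr)) {
    report <- list(
      passband_radius_cyc_per_um = sr$passband_radius,
      pixel_nm = sr$pixel,
      k_est_cyc_per_um = lapply(sr$k_est, as.numeric),
      phases_rad = lapply(sr$phases_est, as.numeric),
      params = unclass(sr$params)
    )
    p <- paste0(prefix, "_report.yml")
    yaml::write_yaml(report, p)
    written <- c(written, p)
  }
  invisible(written)
}
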