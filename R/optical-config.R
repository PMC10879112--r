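#' Optical configuration of the SIM instrument
#'
#' Bundles the parameters that fix every spatial and frequency scale in the
#' simulator and reconstructor: objective NA and magnification, excitation
#' and emission wavelengths, and the physical pixel pitches of the camera
#' and of the spatial light modulator (SLM).  The sample-plane pixel sizes
#' are always derived from these (`camera_pixel / magnification`), never
#' stored separately.
#'
#' @param na Numerical aperture of the objective (0 < na <= 1.7).
#' @param magnification Objective magnification (> 0).
#' @param lambda_ex Excitation wavelength in nm (dominant LED wavelength).
#' @param lambda_em Emission wavelength in nm.  The fluorophores' emission
#'   spectra are reduced to a single dominant wavelength; 515 nm is a
#'   typical green emission for blue (460 nm) excitation.
#' @param camera_pixel Camera pixel pitch in micrometres.
#' @param slm_pixel SLM (LCOS microdisplay) pixel pitch in micrometres.
#'   The default of 5.2 um gives a 52 nm SLM pixel in the sample plane at
#'   100x, commensurate (4:5) with the 65 nm camera sample pixel.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' sample_pixel(cfg)          # 65 nm
#' widefield_cutoff(cfg)      # emission cutoff, cycles/um
#' @export
optical_config <- function(na = 1.3, magnification = 100,
                           lambda_ex = 460, lambda_em = 515,
                           camera_pixel = 6.5, slm_pixel = 5.2) {
  stopifnot(is.numeric(na), length(na) == 1)
  if (!(na > 0 && na <= 1.7)) {
    stop("`na` must lie in (0, 1.7]", call. = FALSE)
  }
  if (magnification <= 0) stop("`magnification` must be > 0", call. = FALSE)
  if (lambda_ex <= 0 || lambda_em <= 0) {
    stop("wavelengths must be > 0", call. = FALSE)
  }
  if (camera_pixel <= 0 || slm_pixel <= 0) {
    stop("pixel pitches must be > 0", call. = FALSE)
  }
  structure(
    list(na = na, magnification = magnification,
         lambda_ex = lambda_ex, lambda_em = lambda_em,
         camera_pixel = camera_pixel, slm_pixel = slm_pixel),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  NA %.2f, magnification %gx\n", x$na, x$magnification))
  cat(sprintf("  excitation %g nm, emission %g nm\n",
              x$lambda_ex, x$lambda_em))
  cat(sprintf("  camera pixel %g um -> sample pixel %.2f nm\n",
              x$camera_pixel, sample_pixel(x)))
  cat(sprintf("  SLM pixel %g um -> %.2f nm in sample plane\n",
              x$slm_pixel, slm_sample_pixel(x)))
  invisible(x)
}

#' Derived sample-plane pixel sizes
#'
#' `sample_pixel()` is the camera pixel projected into the sample plane;
#' `slm_sample_pixel()` is the SLM pixel projected into the sample plane.
#' Both in nanometres.
#'
#' @param config An [optical_config()].
#' @return Pixel size in nm.
#' @export
sample_pixel <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  config$camera_pixel / config$magnification * 1000
}

#' @rdname sample_pixel
#' @export
slm_sample_pixel <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  config$slm_pixel / config$magnification * 1000
}

#' Widefield (incoherent) cutoff frequency
#'
#' The incoherent optical transfer function has support up to
#' `nu_c = 2 NA / lambda`.  The role selects the wavelength: the excitation
#' cutoff limits how fine an illumination pattern can be projected onto the
#' sample, the emission cutoff limits what the detection path transmits.
#'
#' @param config An [optical_config()].
#' @param role `"emission"` or `"excitation"`.
#' @return Cutoff frequency in cycles/um.
#' @examples
#' widefield_cutoff(optical_config(), "excitation")  # 2*1.3/0.460 = 5.652
#' @export
widefield_cutoff <- function(config, role = c("emission", "excitation")) {
  stopifnot(inherits(config, "optical_config"))
  role <- match.arg(role)
  lambda <- switch(role, emission = config$lambda_em,
                   excitation = config$lambda_ex)
  2 * config$na / (lambda / 1000)
}
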