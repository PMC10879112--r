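Package: incosim
Title: Simulation and Reconstruction for Incoherent Structured
    Illumination Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for structured illumination microscopy (SIM) systems in
    which the excitation pattern is formed by imaging a binary spatial light
    modulator (SLM) into the sample plane with incoherent LED light.  The
    package generates binary line-pattern repertoires with matched
    mark-to-area ratio across orientations, simulates raw SIM acquisitions
    through the diffraction-limited incoherent optical transfer function with
    Poisson and read noise, reconstructs super-resolved (SR-SIM, Wiener band
    recombination) and optically sectioned (OS-SIM, square-law) images,
    validates camera/SLM/LED synchronization schedules, and quantifies
    resolution by Gaussian bead fitting and Fourier spectral support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
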