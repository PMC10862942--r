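Package: smpci
Title: Single-Mask X-Ray Differential Phase Contrast Imaging via Transport of Intensity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and single-shot retrieval for single-mask X-ray
    differential phase contrast imaging. A periodic absorption mask placed
    before the object turns refraction into alternating bright and dark
    fringes between adjacent detector pixel columns; a transport-of-intensity
    model reduces the mask's effect to two coefficients, the effective
    aperture and the mask contrast, from which a propagation-based image and
    a differential-phase image can be separated using one sample exposure and
    one flat field. Includes analytic projection phantoms, a Fourier-series
    mask model, the pixel-integrated and closed-form image models, an
    independent angular-spectrum wave-optics simulator for validation,
    Poisson noise, TIFF/CSV image I/O, YAML-configured command-line
    workflows, and a test suite exercising the model's stated approximations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
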