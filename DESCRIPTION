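Package: cryored
Title: Confidence-Weighted Regularization by Denoising for Cryo-EM Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale single-particle cryo-EM refinement engine built around
    marginalized maximum-a-posteriori expectation-maximization with three
    interchangeable maximization steps: the classical Gaussian-prior Wiener
    update, regularization by denoising (RED), and confidence-weighted RED
    (CW-RED), in which a learned volumetric denoiser is blended with the
    Gaussian prior according to the current half-map resolution. Includes a
    Fourier-slice forward model with CTF, a phantom and projection-data
    simulator, training of a volumetric residual U-Net denoiser, Fourier shell
    correlation and angular-error metrics, MRC/STAR input and output, and an
    external-reconstruction file protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
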