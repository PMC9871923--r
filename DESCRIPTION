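Package: campariq
Title: Quantification of Photoconvertible Calcium Integrator Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for photoconvertible calcium integrator
    (CaMPARI-family) two-photon imaging experiments. Computes per-cell
    red-to-green fluorescence ratios (RGR) with dark-current and spectral
    bleed-through corrections, photoconversion light doses, zero-intercept
    dose-response fits, dual-wavelength readout ratios, and the sensitivity
    index (d') separating stimulated from reference cell populations. Also
    analyses dynamic recordings from the green channel of these negative
    calcium indicators: polynomial bleach correction, trial segmentation,
    lowest-quartile delta-F-over-F responses, and ANOVA-based tuned/oriented
    cell classification. Ships a synthetic two-channel image and trace
    generator with planted ground truth so the whole pipeline is testable
    end to end without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, tools, tiff, jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
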