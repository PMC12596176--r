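Package: lungqct
Title: Quantitative CT Phantom Analysis for Low-Dose Lung Protocol Harmonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing low-dose quantitative computed tomography
    (QCT) lung protocols across scanners using an anthropomorphic chest
    phantom. Simulates phantom acquisitions with controlled resolution and
    dose-dependent noise, automatically segments and labels phantom inserts,
    computes Hounsfield-unit densitometry (mean, SD, coefficient of
    variation, low-attenuation-area percentages), estimates the modulation
    transfer function from a cube-edge insert and the noise power spectrum
    from uniform regions, and applies effective-dose arithmetic together
    with a reference-anchored protocol selection rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
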