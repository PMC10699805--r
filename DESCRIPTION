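Package: tmfret
Title: Transition-Metal FRET Distance Analysis for Unroofed-Cell Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for transition-metal ion FRET (tmFRET)
    experiments on unroofed cells. Computes acceptor extinction coefficients
    and donor-acceptor spectral overlap integrals from spectra, Forster radii,
    background-subtracted and photobleach-corrected FRET efficiencies from
    three-stage fluorescence image series, and donor-acceptor distances under
    a point-acceptor geometry (metal chelated at a single cysteine) or a
    planar multi-acceptor geometry (metal-chelating lipids distributed in the
    membrane), with Monte-Carlo verification of the planar model. Includes
    Hill-type fitting of pH-dependent channel activation and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
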