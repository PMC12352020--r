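Package: ribotomo
Title: Ribosome Quantification in Resin-Section Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segment ribosome-sized globular particles in 3D electron
    tomograms of resin-embedded cells, filter detections by size, edge
    contact and plane count, correct particle densities for beam-induced
    section collapse, and convert densities to whole-cell ribosome totals
    using confocal cell-volume measurements. Includes an independent
    biochemical cross-check based on 18S/28S rRNA capillary-electrophoresis
    quantification, and a synthetic-tomogram generator with ground truth so
    every stage can be validated offline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
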