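Package: mtseam
Title: Microtubule Lattice Geometry, Seam Detection, and Dynamic
    Instability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of microtubule lattice
    architecture and dynamics. Builds parametric N-protofilament
    B-lattice models with a ground-truth seam, measures inter-
    protofilament angle profiles and classifies lateral junctions as
    homotypic or heterotypic from labelled coordinates, synthesizes
    tomographic density volumes of decorated microtubules with a
    missing wedge, classifies protofilament number from rotational
    power spectra, scores 8-nm-periodic decoration at each lateral
    junction to call seam-binding proteins, simulates two-state
    dynamic instability, renders TIRF-style kymographs, and recovers
    growth rate, shrinkage rate, lifetime, nucleation time and rescue
    probability from kymographs, including first-triangle and
    5-pixel rescue conventions and dose-response aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
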