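Package: mdxrf
Title: Correlative Mineral Density and X-Ray Fluorescence Mapping of
    Calcified Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates micro-computed-tomography attenuation to
    hydroxyapatite-equivalent mineral density using density phantoms,
    discretizes three-dimensional tomograms into mineral-density segments
    by locus-seeded watershed flooding of the intensity-gradient landscape,
    quantifies X-ray fluorescence elemental maps (Ca, P, Zn) against
    thin-film standards with self-absorption thickness correction, and
    correlates segmented mineral density with Ca/P and Ca/Zn molar ratios.
    Ships a synthetic-data generator emulating phantoms, tissue blocks and
    elemental maps with known ground truth so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
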