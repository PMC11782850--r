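Package: osteovasc
Title: Osteovascular Morphometry from Contrast-Enhanced Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the blood vessel and adipocyte microstructure of long-bone
    marrow from contrast-enhanced micro-computed tomography volumes. Implements
    the full measurement chain: volume-of-interest selection, Otsu bone removal,
    morphological segmentation of marrow adipocytes and vessels with
    partial-volume edge suppression, 3D morphometry (volume fractions, component
    densities, equivalent diameters), model-independent local thickness
    distributions, skeleton-based branching census (branches, junctions, triple
    and quadruple points), geodesic vessel-surface-to-bone-surface distance
    distributions, two-channel immunofluorescence type-H endothelium area
    fractions, and laser Doppler flowmetry trace reduction. Ships a synthetic
    phantom generator with exact ground truth so that every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
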