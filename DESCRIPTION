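Package: laminaq
Title: Lamina-Resolved Quantification of Amyloid Plaque Burden in Mouse
    Hippocampus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, testable re-implementation of a histology workflow for
    quantifying amyloid-beta plaque load across hippocampal subfields (CA1,
    CA2/3, dentate gyrus) and laminae (SO, SP, SR, SLM, MO, SG, hilus) from
    multi-channel immunofluorescence images, together with interneuron-marker
    colocalization counting and group-level statistics. Laminae are segmented
    from a VGLUT1-like neuropil channel, subfields split on a WFS1-like
    channel, plaques masked by Zack/ImageJ Triangle auto-thresholding with a
    strict >10 square-micron particle filter, and burden reported as per-region
    area fractions. A synthetic cohort generator with full ground truth
    (laminar geometry, Poisson plaque fields, hard-core soma maps with
    configurable marker joint tables, ELISA-style concentrations) supports
    end-to-end validation by parameter recovery without any microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
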