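Package: renalvasc
Title: Hybrid Reconstruction of Renal Arterial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs full-scale renal arterial trees by combining
    image-derived priors (a cortex shell approximated from a whole-kidney
    mask and a pre-built large-artery tree extracted from a centerline
    graph) with a modified Global Constructive Optimization (GCO) engine
    that minimizes a combined material and power cost. Terminal
    (afferent-arteriole) positions are drawn by Poisson-disk sampling
    inside the cortex shell. Flows follow Kirchhoff's law, radii follow
    Murray's law, and pressures follow Hagen-Poiseuille's law. Includes a
    synthetic kidney phantom so the whole pipeline runs without any scan,
    Strahler-order morphometry tables, and readers/writers for NIfTI,
    NRRD, SWC, VTK polydata, GraphML and JSON tree formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
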