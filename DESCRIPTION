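Package: voxgex
Title: Voxel-Level Brain Gene Expression Maps, Networks and Cognitive Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for imaging transcriptomics: converts scattered post-mortem
    brain expression samples into dense voxel-by-voxel expression volumes by
    border labelling, Delaunay tessellation and barycentric interpolation;
    summarises regional enrichment against the brain-wide average with FDR
    control and Cohen's d; quantifies donor-to-donor reproducibility with the
    differential stability statistic; builds weighted co-expression networks
    (soft thresholding, topological overlap, module detection) with
    hypergeometric gene-set enrichment; and decodes cognitive-state correlates
    of an expression map against a library of meta-analytic association maps,
    including a permutation contrast between social and non-social terms.
    Ships a synthetic-data generator with planted regional, modular and
    term-linkage structure so every stage can be validated against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
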