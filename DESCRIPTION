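Package: kmerassign
Title: Hierarchical Alignment-Free Species Assignment for Multilocus Amplicon Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species assignment for multilocus targeted amplicon data using k-mer
    distances. Haplotypes are compared alignment-free via normalised k-mer count
    differences; reference samples are partitioned into nested species-groups at
    fine, intermediate and coarse distance thresholds; queries are assigned by
    frequency-weighted nearest-neighbour proportions averaged over targets, with
    hierarchical classification at a configurable proportion threshold. Closely
    related species within a complex are resolved by a variational autoencoder
    over summed diploid 8-mer count tables (Poisson reconstruction loss, Gaussian
    latent regulariser) followed by convex-hull classification in the
    three-dimensional latent space, with fuzzy boundaries and ordered uncertain
    calls. Includes calibrated synthetic data generators, drop-one-out validation
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
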