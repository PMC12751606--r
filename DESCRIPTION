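Package: gcppi
Title: Ab Initio Protein-Protein Interaction Networks from Genomic Context
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free prediction of protein-protein interaction (PPI)
    networks from bacterial and archaeal proteomes. Proteins are described by
    a 60-value propensity descriptor (10 physicochemical scales summed over
    the whole sequence and its start/middle/end regions, plus 20 amino-acid
    counts); protein pairs are called similar either by threshold matching on
    these features or by a trained random-forest classifier. Interactions are
    inferred per genome from conserved phylogenetic profiles (with a
    configurable profile-difference tolerance) and conserved gene
    neighborhoods. Large phylogenetic-profile groups are sparsified by a
    stochastic shuffle-subdivide interaction-sampling algorithm, and a
    replicate-stability suite (weighted global presence mean, pairwise
    Jaccard, adapted Fleiss' kappa, Kendall ratio positive, multi-sample
    Kolmogorov-Smirnov distance) quantifies how well the sampled networks
    preserve the ranking of topologically central nodes. Includes a synthetic
    proteome simulator with full ground truth, DOT export, and edge-list
    comparison arithmetic against reference networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
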