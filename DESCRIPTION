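Package: netent
Title: Multivariate Entropy of Gene Expression and Protein Interaction
    Networks Across Disease Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes multi-stage disease progression (carcinogenesis)
    by the differential entropy of gene expression. Selects differentially
    expressed genes with a double filter (BH-adjusted p-value and fold
    change), maps them onto a cleaned protein-protein interaction graph,
    extracts first-neighbor local networks, and computes multivariate
    Gaussian differential entropies in bits: a global per-stage expression
    entropy, per-node local-network entropies, and the (sign-flipped)
    average network entropy. Stage trajectories are scanned for sudden
    entropy changes (candidate early warnings), local entropies are binned
    into groups anchored on the healthy state, and genes that change group
    between stages are reported as transition genes. A synthetic-study
    generator with known ground-truth covariances and a planted entropy
    shift makes the whole pipeline verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    MASS,
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
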