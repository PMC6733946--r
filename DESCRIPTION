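Package: hyphaevol
Title: Comparative Phylogenomics of Gene Family Evolution at the Origin of
    Hyphal Multicellularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating the origin of a binary organismal trait on a
    species phylogeny and for detecting gene families whose birth, duplication
    and loss dynamics correlate with the designated origin nodes. Implements
    support-thresholded gene-tree/species-tree LCA reconciliation, Dollo
    parsimony gain-loss mapping with ancestral copy-number reconstruction,
    Bayesian threshold-model ancestral state reconstruction of a binary trait,
    Fisher exact enrichment and depletion contrasts, a permutation-ANOVA
    duplication-rate screen with a conservation filter, gene-structure and
    domain-architecture statistics from GFF3 and domain tables, and a fully
    seeded synthetic-data generator that produces ground-truth histories for
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
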