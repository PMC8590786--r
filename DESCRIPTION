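Package: coexqtl
Title: Systems Genetics of Lignocellulose Regulators via Co-Expression
    Networks and eQTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for nominating candidate regulators of
    stone-cell lignocellulose formation in pear fruit from a population
    expression panel. Implements weighted co-expression module detection
    (soft-thresholded adjacency, topological overlap, eigengene merging),
    module- and gene-trait association, an all-pairs SNP-by-gene eQTL scan
    with latent-factor and genotype-PC covariates, leading-SNP collapsing
    with local/distant classification, permutation-based trans-eQTL hotspot
    calling, a targeted transcription-factor by structural-gene network with
    permutation hub calling, eQTL-region by co-expression intersection for
    regulator prioritisation, and a protein motif scan for secondary-cell-
    wall NAC signatures. Ships a synthetic-data generator with planted,
    recorded ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
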