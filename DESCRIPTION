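Package: phenowalk
Title: Disease-Gene Prioritization by Random Walk with Restart on a
    Three-Layer Phenotype-Gene Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate disease genes by propagating probability mass
    from known disease genes and disease phenotype nodes through a
    heterogeneous graph built from two disease-phenotype similarity
    networks and one gene functional network, joined by bipartite
    disease-gene association and cross-vocabulary mapping links. Provides
    the block-normalized transition matrix, the random walk with restart
    with an exact linear-solve oracle, gene ranking with rank percentages,
    leave-one-out cross validation, binned enrichment with fold-enrichment
    and permutation p-values, precision-recall curves, top-k pathway
    scoring from GMT gene sets, a synthetic planted-module network
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
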