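Package: phylodist
Title: Linear-Time Evolutionary Distinctiveness Indices on Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes per-taxon evolutionary distinctiveness indices on
    edge-weighted phylogenetic trees: the phylogenetic Shapley value, the
    heightened evolutionary distinctiveness (HED) score under per-taxon
    extinction probabilities, and the fair proportion (FP) index with its
    EDGE product.  Shapley and HED are computed by a linear-time arc
    traversal that updates edge coefficients along a planar leaf ordering,
    so complete multi-tree posterior samples with thousands of tips can be
    scored quickly.  Includes exhaustive definitional oracles for testing,
    mapping of IUCN Red List categories to extinction probabilities, a Yule
    (pure-birth) tree simulator, batch scoring of multi-tree Newick files
    with across-tree summaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    withr
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
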