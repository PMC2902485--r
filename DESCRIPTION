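Package: phytarget
Title: Exact Edge-Disjoint Leaf Pairing on Phylogenetic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact solvers for the maximal pairing problem on rooted
    phylogenetic trees: find a maximum-weight set of pairwise edge-disjoint
    leaf-to-leaf paths, the combinatorial core of phylogenetic targeting and
    phylogenetically independent pairwise comparisons. Provides a dynamic
    program for binary trees, a generalization to multifurcating trees via
    maximum-weight matchings on auxiliary graphs built from each polytomy's
    children, constrained variants (bounded pair count, required taxa,
    prescribed pairs), and a Boltzmann-ensemble version with per-pair
    selection probabilities. Includes a brute-force enumeration oracle,
    seeded random tree and weight generators, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
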