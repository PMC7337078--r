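Package: tsdual
Title: Site, Branch, and Node Statistics on Succinct Tree Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A general framework for single-site population-genetic
    statistics on succinct tree sequences.  Statistics are defined by a
    pair of sample weights and a summary function, and are computed in
    three dual modes: Site (from allele weights at segregating sites),
    Branch (from branch lengths and subtree weights), and Node (per-node
    span-weighted averages).  The package provides an incremental
    weight-propagation engine that updates subtree weights between
    adjacent marginal trees, recipes for named statistics (nucleotide
    diversity, divergence, segregating sites, Patterson's f4, trait
    correlation, Tajima's D, ancestry proportions), Poisson mutation
    dropping under the infinite-sites model, coalescent simulators
    (single population with recombination, structured with migration),
    brute-force reference implementations, and Monte-Carlo checks of the
    site/branch duality and its variance decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
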