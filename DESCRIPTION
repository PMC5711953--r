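Package: blindtree
Title: Retrotransposon Presence/Absence Phylogenetics Under
    Single-Reference Ascertainment Bias
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical framework for phylogenetic inference from
    retrotransposon presence/absence markers when loci were ascertained
    in a single reference genome, so that support for clades excluding
    the reference taxon (the "blind" tree) is unobservable.  Provides
    exact cumulative-binomial KKSC support tests in their
    multi-directional and one-directional forms, a two-tailed symmetry
    test against incomplete lineage sorting, an insertion ratio test
    against introgression/hybridization with the bound N = gamma (d + e)
    on introgressed marker sharing, Dollo-logic polarization of marker
    matrices onto a rooted species tree, trifurcation and ratio counting,
    a three-argument blind-tree decision workflow, and a coalescent-style
    simulator for probing test calibration under hemiplasy and
    introgression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
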