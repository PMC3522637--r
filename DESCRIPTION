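Package: patroclad
Title: Patrocladistic Classification and Desk-Scale Parsimony Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for patrocladistic classification of taxa on rooted
    phylogenies: pairwise p- and Kimura 2-parameter genetic distances with
    group means, a small-parsimony engine (Fitch/Hartigan lengths, ancestral
    state reconstruction, per-branch apomorphic change counts, exhaustive and
    NNI tree search, nonparametric bootstrap, strict and majority-rule
    consensus), cladistic and patristic distance matrices combined and
    clustered by UPGMA into a patrocladogram, monophyly diagnosis with
    intruder identification and minimum independent-origin counting for
    character states, and a synthetic-data generator (Yule trees, K2P
    sequence evolution, Mk morphological characters, and a planted-paraphyly
    scenario) so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
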