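Package: rfpaths
Title: Monotone Robinson-Foulds Paths in Tree Rearrangement Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the Robinson-Foulds (RF) distance behaves
    along paths in phylogenetic tree rearrangement graphs. Represents unrooted
    binary trees by their split sets, applies and enumerates Nearest Neighbor
    Interchange (NNI), Subtree Prune and Regraft (SPR) and Tree Bisection and
    Reconnection (TBR) moves, and constructs, for any two trees on the same
    leaf set, an NNI path along which the RF distance to the target never
    increases and an SPR path along which it strictly decreases at every step.
    Includes exhaustive treespace machinery (enumeration of all small
    topologies, breadth-first graph distances) and a search for tree pairs
    admitting no strictly RF-decreasing NNI step, together with seeded uniform
    random topology generation and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    igraph
Config/testthat/edition: 3
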