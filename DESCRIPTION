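Package: traitgraph
Title: Trait Co-Occurrence Networks from Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recodes characters-by-taxa morphological matrices into
    presence/absence traits, classifies every cross-character pair of traits
    into one of four co-occurrence relations (identical, nested, overlapping,
    disjoint), and assembles the resulting multiplex trait network. Computes
    exact network statistics (complexes, type II in/out degrees, type III
    density, triangles and diameter, type D triplets) and assesses their
    significance with equiprobable and phylogenetically restricted
    permutation tests against a reference tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
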