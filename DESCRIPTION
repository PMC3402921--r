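Package: stackpath
Title: Stack-Guided Search for Low-Barrier RNA Refolding Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts low energy-barrier folding pathways (direct and
    indirect) between two pseudoknot-free secondary structures of an RNA
    sequence. Pathways are represented as action chains of base-pair
    additions and deletions and evolved with mutation operators that
    reorder actions, insert complementary action pairs, and force the
    formation or cooperative conversion of helical stacks, selecting on
    the energy barrier under a nearest-neighbour free-energy model.
    Includes an adapter to ViennaRNA's RNAeval for Turner energies, a
    dependency-free simplified energy model, an exact minimax solver for
    optimal direct pathways on small instances, and a synthetic instance
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
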