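Package: filamentcover
Title: Decomposing Weighted Geometric Networks into Individual Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a weighted geometric graph, such as a cytoskeletal or
    neuronal network extracted from image data, into an optimal set of
    individual filaments by solving the filament cover problem: candidate
    edge-paths are sampled by an angle-constrained breadth-first search or
    from random minimal spanning trees, scored by intensity-based roughness
    functionals, and selected by an exact set-cover optimisation minimising
    total or average roughness. Includes structure-aware Rand and Jaccard
    partition-similarity indices for edge covers, per-filament shape and
    intensity analytics, a planted-scene simulator with crossing,
    overlapping, and looped filaments, and robustness protocols against
    edge loss and weight noise. Graphs are read and written in the GML
    format; filament tables are written as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    clue,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
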