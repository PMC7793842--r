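Package: hgpm
Title: Hierarchical Graph Representation of Pharmacophore Model Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts large ensembles of interaction-based pharmacophore
    models, such as one model per frame of a molecular dynamics trajectory,
    into counted unique feature vectors, builds the subset/superset hierarchy
    of the unique models (including artificial intersection nodes and
    transitive reduction to the cover relation), lays the graph out
    deterministically with a one-dimensional multidimensional scaling of
    Manhattan distances, and drives pharmacophore-model selection and
    consensus virtual-screening scoring (truncated ROC AUC) from the graph.
    Includes readers and writers for model sets, JSON and GraphML graph
    exports, a standalone interactive HTML rendering, a command-line
    interface, and a seeded synthetic generator of MD-like ensembles and
    matched screening libraries for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
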