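Package: hyperora
Title: Over-Representation Analysis of Gene Lists Against Curated
    Annotation Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests one or more query gene lists for over-representation
    (and depletion) of curated gene-set annotations using the
    hypergeometric upper-tail probability, with two background-resolution
    modes (intersection with each dataset's gene universe, or the user
    background as supplied), global Benjamini-Hochberg false discovery
    rate control across all query-by-annotation comparisons, GMT
    collection input and output, an individual-gene lookup, a
    Jaccard-weighted annotation-overlap network with per-query
    significance overlays, heatmap and table reporting, seeded synthetic
    fixture generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
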