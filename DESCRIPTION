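Package: pathspace
Title: Gene-List Proximity Testing and Density Landscapes in Pathway Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embeds a gene-interaction graph with a fixed two-dimensional
    layout ("pathway space"), projects gene-list signal into a smoothed
    density landscape restricted to the graph silhouette, and statistically
    tests whether two gene lists lie closer together in pathway space than
    expected by chance. The test statistic is the average shortest-path
    (hop-count) distance from each gene in one list to its first nearest
    neighbor in the other list; significance is assessed against a
    permutation null built from random vertex lists of matching sizes, with
    an empirical left-tail p-value and a z-score for cross-comparison of
    unequal list sizes. Includes readers for GraphML, edge-list/layout TSV,
    two-column gene-list CSV and GMT gene-set files, a hypergeometric
    overlap test, synthetic graph and gene-list generators for simulation
    studies, and plotting of graph space, density landscapes and null
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
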