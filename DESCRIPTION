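Package: linkclust
Title: Multi-Source Record Linkage via Blocking and Complete-Linkage
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links records referring to the same individual across several
    tabular data sources without a shared universal identifier.  The pipeline
    collapses exact duplicates by radix-sorting records of attribute-comparable
    dataset pairs, restricts candidate comparisons with k-mer blocking,
    scores candidates with threshold-bounded (banded) edit distances, extracts
    single-linkage components from the threshold graph, and then re-clusters
    each component with agglomerative complete linkage so that no output
    cluster has a diameter above the threshold, followed by a
    priority-attribute refinement pass.  Includes seedable synthetic dataset
    generators with ground truth, a Type I-IV / majority-owner accuracy
    evaluator, a deterministic parallel executor, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    parallel,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
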