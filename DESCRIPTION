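Package: coexmod
Title: Condition-Independent Weighted Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from multi-batch
    expression compendia using the biweight midcorrelation, selects a soft
    threshold by the scale-free topology criterion, computes the topological
    overlap matrix, detects co-expression modules by dynamic hybrid cutting of
    the average-linkage dendrogram, merges modules with correlated eigengenes,
    assesses module stability by half-sample resampling of intramodular
    connectivity, and performs downstream analysis: hub gene selection,
    hypergeometric association of modules with stress gene lists, term
    enrichment, transcription-factor ranking against module hubs, and
    guilt-by-association annotation of uncharacterized hub genes. Includes a
    synthetic-data generator with planted modules, hubs, regulators and trait
    lists so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, igraph
Suggests: testthat (>= 3.0.0), mclust, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
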