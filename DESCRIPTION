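Package: seedpath
Title: Seed-Based Candidate Gene Discovery on Weighted Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers candidate genes for a biological process from a weighted
    protein-protein interaction network and a set of seed genes annotated to the
    process. Interaction confidence scores (STRING-style combined scores in
    150-999) are transformed to edge weights 1000 - score, all shortest paths
    between seed-gene pairs are computed with Dijkstra's algorithm, and every
    non-seed gene interior to at least one such path becomes a candidate, scored
    by the number of seed-pair shortest paths through it (path betweenness).
    Candidates are filtered by a permutation false discovery rate obtained from
    random same-size gene sets, and the survivors can be tested for
    over-representation in named gene-set collections with an exact
    hypergeometric upper-tail test. A synthetic network generator with planted
    seed modules and bridge genes provides ground truth for end-to-end testing
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
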