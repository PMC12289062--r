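Package: ktdrank
Title: Node Influence Ranking by K-Shell Iteration, Degree and Neighbor
    Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies influential spreaders in undirected networks with the
    KTD score: a k-shell decomposition that records a global iteration factor
    for every node, a degree-refined within-shell influence, and aggregation
    over neighbor influences. Ships the evaluation stack used in the
    influential-spreader literature: the ranking monotonicity index, dense
    rankings with CCDF and rank-frequency summaries, a discrete-time SIR
    spreading simulator with per-node spreading power and top-k seed curves,
    the mean-field epidemic threshold, Kendall rank agreement (tau-a and
    tau-b), and degree/betweenness/closeness/k-shell baseline centralities,
    plus edge-list I/O, synthetic graph generators and the Zachary karate
    club fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
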