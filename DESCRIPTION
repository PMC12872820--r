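Package: temporalmapper
Title: Attractor Transition Networks from Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs attractor transition networks from uniformly sampled
    multivariate time series using spatiotemporal k-nearest-neighbor (STKNN)
    graphs and shortest-path contraction. Nodes of the contracted network are
    clusters of time points interpreted as attractor-like metastable states;
    node size measures total dwell time (local stability) and directed loop
    length measures recurrence difficulty (global stability). Includes
    interval-coded annotation overlays, a within-session / between-session
    nonparametric statistical design (Spearman rank correlations and one-sample
    Wilcoxon signed-rank tests with exact small-sample enumeration), and a
    seeded generator of multistable dwell-escape dynamics with ground-truth
    labels for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
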