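Package: fossilnet
Title: Temporal Multilayer Network Analysis of Fossil Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects biotic transitions in dated fossil occurrence records by
    assembling taxon- and trait-based temporal multilayer networks and
    clustering them with the multilayer map equation (relaxed random walks
    over ordered time layers).  Includes a synthetic fossil-record generator
    with planted temporal regimes, filtering and time-binning of dated
    samples, bootstrap assessment of module significance (significant cores,
    abrupt versus gradual transitions, per-layer robustness), mutual climatic
    range (MCR) palaeotemperature reconstruction per module with jackknife
    resampling, and indicator value (IndVal) analysis of trait flows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
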