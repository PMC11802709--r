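Package: flocknet
Title: Association Definitions and Social Networks from RFID Detection Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gambit-of-the-group social networks from timestamped RFID
    detections of PIT-tagged animals at feeders, under three association
    definitions: a strict time-window chain rule, Gaussian-mixture gathering
    events, and arrival-time overlap. Builds simple-ratio-index weighted
    networks, compares networks across definitions (Jaccard edge and triangle
    similarity, MRQAP regression, Mantel tests) with pre-network permutation
    nulls, estimates between-week repeatability of individual network
    positions by variance components, and sweeps the time-window parameter
    for sensitivity analysis. Includes a fission-fusion flock-foraging
    simulator for validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    mclust,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
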