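Package: beadphage
Title: Simultaneous Quantification of Phagocytosis and Migration from
    Phase-Contrast Time-Lapse Microscopy
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies opsonin-independent phagocytosis of Dynabeads and
    spontaneous migration of phagocytes from phase-contrast time-lapse
    sequences. Detects bead conglomerates per frame, classifies them as
    cell-free or ingested, counts beads per conglomerate through a
    size-brightness diagram, links detections into tracks by optimal
    assignment, derives raw, robust-regression-smoothed and Euclidean
    migration paths with per-cell and per-group speed statistics, and
    reconstructs cumulative ingestion curves with per-cell and per-bead
    normalization. Includes a seeded synthetic time-lapse generator with
    ground truth for validation, flow-cytometry mean-fluorescence-intensity
    background subtraction, and unpaired two-group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
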