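Package: plqsar
Title: Topological QSAR Modelling and Similarity Screening of Pancreatic
    Lipase Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates 2D-QSAR multiple linear regression models
    of pancreatic lipase inhibition (pIC50) from topological molecular
    descriptors, and screens candidate natural-product libraries by
    fingerprint similarity. Implements centered Broto-Moreau (ATSC), Moran
    (MATS) and Geary (GATS) autocorrelation descriptors, Burden-modified
    matrix eigenvalue descriptors (SpMin_Bh) and the Randic-like eigenvector
    index on the topological distance matrix (VR_D); a correlation
    pre-filter; genetic-algorithm descriptor subset selection with
    ordinary-least-squares fitting; the full validation suite (R2, adjusted
    R2, MAE, RSS, SDEC, leave-one-out Q2); circular fingerprint Tanimoto
    enrichment with mini-batch k-means library clustering; and seeded
    synthetic-data generators plus an embedded 40-flavonoid benchmark for
    offline, reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
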