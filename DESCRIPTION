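Package: icdensity
Title: Image Sample-Size Determination for Corneal Immune-Cell Density
    from In Vivo Confocal Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines how many non-overlapping in vivo confocal microscopy
    (IVCM) images are required to estimate corneal epithelial immune-cell
    density within a stated precision of a participant's reference ("true")
    mean. Implements exhaustive enumeration of k-image subsets of a 16-image
    reference set, the mean-ratio statistic and its finite-population
    closed-form standard deviation, tolerance-style confidence bands with a
    minimal-sample-size decision rule, single-rating two-way random-effects
    intraclass correlation coefficients (absolute agreement and consistency)
    with F-based confidence intervals, and a simulation of observer image
    selection bias with Student's t and F comparisons against the exhaustive
    random-subset reference. A seeded synthetic count generator emulates the
    study design (20 participants, 16 images per corneal region, gamma
    participant heterogeneity, Poisson or negative-binomial counting noise)
    so the full pipeline is testable without access to raw counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
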