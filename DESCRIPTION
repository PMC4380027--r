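Package: ampsieve
Title: Family-Specific Feature Profiling of Antimicrobial Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles antimicrobial peptide (AMP) families by a region-based
    compositional encoding of peptide sequences, mining of family-specific
    "restrictive" physicochemical properties from AAIndex-style amino-acid
    property scales, and genetic-algorithm feature selection that drives
    unsupervised k-means clustering to separate one target family from all
    other peptides. Includes a progressive multiple sequence aligner, a full
    external cluster-evaluation battery (accuracy, sensitivity, specificity,
    precision, F-measure, Jaccard index, entropy, purity), and a seeded
    synthetic-data generator that plants per-region compositional biases and
    bounded physicochemical property values so every pipeline stage can be
    exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
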