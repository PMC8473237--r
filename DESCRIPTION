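Package: megcoh
Title: MEG Source-Space Coherence Connectivity and Wavelet Neuromarkers for MCI Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a source-space magnetoencephalography (MEG) analysis
    pipeline for discriminating mild cognitive impairment (MCI) from healthy
    controls (HC): epoch-wise magnitude-squared spectral coherence over ten
    cortical regions of interest, per-region degree-of-connectivity statistics,
    partitioning of regions into hyper- and hypo-connected groups, wavelet-packet
    "approximate-derivative standard deviation" neuromarkers, and dual
    cross-validation evaluation (Monte-Carlo repeated splits versus subject-wise
    leave-one-out) with the accompanying statistical screening under
    Holm-Bonferroni correction. A synthetic-cohort generator with planted
    coherence and spectral class effects stands in for non-public MEG data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nortest,
    MASS,
    class,
    e1071,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
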