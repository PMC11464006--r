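Package: atacdeconv
Title: Cell-Type Deconvolution of Bulk ATAC-Seq Data with Reference
    Chromatin-Accessibility Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates immune, stromal and vascular cell-type proportions,
    together with the fraction of uncharacterized (e.g. malignant) cells,
    from bulk ATAC-Seq count matrices by weighted constrained least-squares
    deconvolution against reference chromatin-accessibility profiles.
    Includes the upstream pipeline that builds such references from sorted
    samples: reproducible consensus peak merging, TMM-normalized pairwise
    differential accessibility with empirical-Bayes moderated t-tests,
    fold-stability and chromatin-module filtering of cell-type-specific
    marker peaks, and TPM-like reference profile construction. A seeded
    synthetic-data generator and Pearson/RMSE benchmarking utilities
    support validation against known mixing proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR,
    limma,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
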