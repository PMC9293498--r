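Package: lrbsf
Title: Cumulant-Driven Likelihood-Ratio Decoding of Event-Related fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate pattern analysis (MVPA) decoder for event-related
    BOLD fMRI built around likelihood-ratio-based score fusion (LRBSF).
    Trial-wise beta-series general linear model estimation, t-statistic
    voxel selection, compression of each trial's voxel pattern into
    second- and fourth-order moment/cumulant features, kernel-density
    class-conditional likelihoods with likelihood-ratio (binary) and
    max-score (multiclass) decisions, and Monte-Carlo cross-validation
    protocols. Includes a synthetic BOLD generator with known ground
    truth so the full pipeline is testable end to end, plus NIfTI-1,
    TSV and CSV interfaces and a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
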