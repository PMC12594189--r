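Package: digitME
Title: Measurement Error and Time-Lag Bias in 2D Landmark Digitization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying digitization measurement error (ME) in
    landmark-based geometric morphometrics. Implements TPS landmark file
    input/output, generalized Procrustes superimposition with tangent-space
    diagnostics, hierarchical Procrustes ANOVA, the measurement-error ANOVA
    separating systematic from random digitization error with signal-to-noise
    ratio permutation tests and eigenvector (EV) ordination, per-landmark
    absolute-imprecision scoring with threshold-based configuration reduction,
    robustness tests of sexual dimorphism and static allometry across repeated
    digitizations, and a biased-design ("visiting scientist") simulation. A
    synthetic digitization generator with known ground truth supports parameter
    recovery and type-I error studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
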