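Package: deconvbench
Title: Simulation and Evaluation Harness for Benchmarking Bulk RNA-Seq
    Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates heterogeneous bulk RNA-seq mixtures with known
    cell-type composition for benchmarking deconvolution methods.
    Mixtures are assembled as M = S x W + noise from purified source
    profiles S and designed weight matrices W under three noise models
    (normal, log-normal, and gamma-Poisson/negative binomial) across
    graded noise levels, controlled library sizes, four weight-matrix
    regimes (orthog, real, dominant, uniform), and tumor spike-ins of
    unknown content.  Includes marker- and signature-gene selection,
    a built-in non-negative least squares baseline, dual-metric scoring
    (Pearson r and mean absolute deviance with NA penalties) on both
    absolute and relative proportion scales, and variance-structure
    diagnostics (mean-variance trend, CV density, sample concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
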