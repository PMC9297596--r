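Package: rdcnv
Title: Germline Copy Number Variant Calling from Targeted Read-Depth Data
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects germline copy number variants (CNVs) from multi-sample
    read-count matrices produced by hybridization-capture sequencing panels
    and exomes. Depth matrices are log-transformed, median-centered per
    sample, and denoised by removing the top right singular vectors within
    strided target partitions. Per-target, per-copy-state Gaussian emission
    distributions are estimated by rescaling background depths with
    pseudo-CNV coefficients and re-applying the normalization, and a
    five-state homogeneous hidden Markov model is decoded by pointwise
    maximum a posteriori (PMAP) to emit quality-scored CNV calls. Includes a
    count-level spike-in simulator with latent batch structure and an
    evaluation module implementing reciprocal-overlap and target-Jaccard
    benchmarking with F1-based quality-threshold optimization.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
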