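Package: fmqreg
Title: Quantile Regression for White Matter Fiber Bundle Microstructure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical analysis of white matter fiber bundle
    microstructure (e.g., fractional anisotropy from diffusion-MRI
    tractography) using quantile-specific bundle regions. Pools
    streamline-point values across a cohort into a population fiber
    bundle, partitions it into equal-size regions by value quantiles
    from bundle periphery to bundle core, and fits a pooled linear
    quantile regression per region with cluster-robust (subject-level)
    sandwich inference and Benjamini-Hochberg false discovery rate
    control. Includes the two standard comparison analyses (whole-tract
    mean regression and along-tract profile regression), mean-squared
    error model-fit evaluation, a synthetic multi-subject bundle
    generator with known quantile-varying effects, and readers/writers
    for streamline bundles with per-point scalars (long-table CSV, TRK,
    TCK with scalar sidecar).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    quantreg,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
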