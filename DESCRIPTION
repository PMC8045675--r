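Package: mbwsim
Title: Activator-Inhibitor Modelling and Knockdown Transcriptomics of the
    MBW Anthocyanin Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the MBW (MYB-bHLH-WD40) anthocyanin regulatory
    network as a minimal activator-inhibitor system with RNAi knockdown,
    performs linear (Turing) stability analysis and reaction-diffusion
    patterning on a two-zone petal domain, generates synthetic
    negative-binomial RNA-seq count matrices with the regulator/EBG/LBG
    effect-size structure of a wild-type versus RNAi petal experiment, and
    runs a small-replicate differential-expression stage (median-of-ratios
    normalization, moment dispersion estimation with shrinkage, Wald tests
    with Benjamini-Hochberg correction) whose planted-effect recovery is
    validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
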