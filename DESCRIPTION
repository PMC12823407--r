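Package: specdrift
Title: Trait Specificity, Coding Length and Genetic Drift in GWAS and
    Burden-Test Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and simulators for understanding what genome-wide
    association studies (GWAS) and rare-variant loss-of-function (LoF)
    burden tests actually prioritize. Computes equilibrium allele-frequency
    spectra under heterozygote selection with a discrete-time Wright-Fisher
    chain and a diffusion oracle, simulates pleiotropic squared effect
    sizes with tunable cross-trait correlation, generates GWAS and burden
    summary statistics with Gaussian estimation noise, and implements
    unbiased trait-importance estimators, s_het binning with z-squared
    heritability enrichment, heritability-flattening analyses, GWAS locus
    grouping and ranking algorithms, hit-pleiotropy quartile profiles, and
    tissue-specificity proxies from expression and chromatin-accessibility
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
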