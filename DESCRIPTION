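Package: hapcgr
Title: Chaos Game Representation Analysis and Gap Imputation for Binary
    Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps binary SNP haplotype sequences into chaos-game coordinate
    series and analyzes them as nonlinear time series. Haplotypes are split
    into dense SNP subsequences by genomic distance, encoded by the iterative
    midpoint (chaos game) map, and tested for deterministic structure with
    phase-randomized surrogate data on the Grassberger-Procaccia correlation
    dimension together with Eckmann Lyapunov spectra. Fixed-size box-counting
    multifractal spectra quantify the scaling of the resulting point sets.
    The same phase-space reconstruction drives a local-projection method that
    imputes alleles at uncovered or low-coverage sites of a haplotype
    assembly. Includes seeded generators for chaotic and stochastic binary
    sequences, clustered SNP positions, binomial cascade measures with
    closed-form spectra, and simulated sequencing fragment matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
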