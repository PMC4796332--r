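Package: himalhap
Title: Archaic EPAS1 Haplotype Analysis for Himalayan Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the Denisovan-derived EPAS1 core haplotype in
    Himalayan populations from multiplexed SNP genotypes: genotype quality
    control (sex-discordance, sample and SNP missingness, duplicate
    concordance), EM haplotype phasing, core-motif haplotype frequency
    estimation and altitude correlation, median-joining haplotype networks,
    hierarchical Bayesian estimation of scaled selection coefficients under
    Wright's island model, genotype-altitude association under additive,
    dominant and recessive codings, and two-population Wright-Fisher forward
    simulation of the selection scenario. Includes a synthetic-data generator
    that emulates the multi-population study design so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
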