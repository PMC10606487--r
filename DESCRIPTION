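Package: edsplink
Title: Extreme Discordant Sib-Pair Linkage Analysis for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for sib-pair linkage studies of
    quantitative traits such as blood pressure. Simulates nuclear families
    segregating a biallelic quantitative-trait locus together with linked
    multi-allelic microsatellite markers, selects extreme discordant sib
    pairs, estimates identity-by-descent allele sharing from sibling
    genotypes without parental data, and tests for linkage by Haseman-Elston
    regression, Pearson correlation, covariate-adjusted regression and an
    allele-sharing likelihood-ratio test. A Monte Carlo power module compares
    extreme-discordant against unselected and affected-pair designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
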