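Package: groupBH
Title: Group-Adaptive Benjamini-Hochberg FDR Control for Paired qPCR
    miRNA Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grouped false-discovery-rate analysis for paired qPCR
    (delta-Ct) microRNA expression data. Implements directional paired
    delta-delta-Ct t-tests on complete cases, genomic position-based
    grouping schemes (chromosome, strand, arm, and max-group-size
    refinements), the group-adaptive Benjamini-Hochberg procedures
    TST-GBH and LSL-GBH, group SABHA with tau-censored null-proportion
    estimates, a random-group-assignment control study, intra- and
    inter-group correlation diagnostics under an exchangeable
    random-effects model, and a seeded synthetic miRNAome generator with
    detection-limit (MNAR) missingness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
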