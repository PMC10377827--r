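Package: mirct
Title: Fold-Regulation Analysis of Serum miRNA qPCR Array Ct Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of circulating microRNA profiles measured by real-time
    PCR arrays, from raw cycle-threshold (Ct) tables to differential
    fold-regulation signatures. Implements sample quality control (hemolysis
    delta-Ct index, RNA purity ranges, detection filtering, expression tiers),
    three interchangeable normalization strategies (global Ct mean, endogenous
    reference genes, exogenous spike-in), delta-delta-Ct fold change and signed
    fold regulation with threshold-based classification, signature rules for
    disease-progression and condition-specific markers, a synthetic cohort
    simulator with planted effects for parameter-recovery testing, and
    non-parametric clinical covariate summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
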