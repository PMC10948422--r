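Package: mrcoloc
Title: Bidirectional Two-Sample Mendelian Randomization and Bayesian
    Colocalization for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for causal inference between complex traits from GWAS
    summary statistics: reading and harmonizing summary-statistic tables,
    selecting independent genetic instruments (LD clumping, minor-allele
    frequency and instrument-strength filters, confounder blocklists),
    estimating causal effects with inverse-variance weighting, MR-Egger,
    weighted and simple median, and weighted mode estimators, a full
    sensitivity suite (Cochran's Q, Egger intercept, I2GX, MR-PRESSO
    outlier detection, leave-one-out), Benjamini-Hochberg false discovery
    rate control with significance tiers, Bayesian colocalization via
    Wakefield approximate Bayes factors, and a seeded synthetic GWAS
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
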