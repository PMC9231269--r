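Package: metabomr
Title: Two-Sample Univariable and Multivariable Mendelian Randomisation
    for Metabolic Trait Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-sample Mendelian randomisation workflow for
    prioritising candidate metabolic exposures affecting a continuous
    outcome from GWAS summary statistics: harmonisation of exposure and
    outcome association tables (including palindromic-SNP resolution by
    allele frequency), greedy LD clumping, trait-panel reduction
    (ratio/composite exclusion, lipoprotein-subclass selection, genetic
    correlation pruning), univariable MR (Wald ratio, inverse-variance
    weighted, mean F, Cochran's Q, leave-one-out), pleiotropy-robust
    estimators (MR-Egger, weighted median, weighted mode with parametric
    bootstrap), and multivariable MR with conditional F-statistics and a
    heterogeneity Q-statistic. A synthetic summary-statistics generator
    with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
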