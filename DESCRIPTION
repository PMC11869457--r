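Package: salmeta
Title: Multi-Population GWAS by Mega- and Meta-Analysis with Secondary-Signal Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-linear-model genome-wide association within and across
    related aquaculture-like populations. Provides a synthetic generator for
    multiple admixed populations with family structure, a major QTL and an
    ordinal liability-threshold phenotype; joint genotype quality control
    (call rate, MAF, exact Hardy-Weinberg test, heterozygosity band);
    VanRaden genomic relationship matrices with REML variance components and
    generalized-least-squares association scans; mega-analysis with a
    population fixed effect; Stouffer Z-score, inverse-variance-weighted and
    Han-Eskin random-effects meta-analysis with Cochran's Q, I-squared and
    DerSimonian-Laird tau-squared; genomic-control inflation diagnostics and
    Benjamini-Hochberg FDR thresholds; and three secondary-signal procedures
    (iterative conditional association, approximate conditional and joint
    selection from summary statistics, and LD clumping).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
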