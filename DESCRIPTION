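Package: kinreject
Title: Parentage Verification and Genotyping-Error Estimation by Genetic
    Exclusion on Dense SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Verifies or discovers first-degree (parent-offspring)
    relationships among densely genotyped diploid individuals using the
    opposing-homozygote exclusion statistic: the rate at which a pair of
    individuals is homozygous for alternative alleles across SNPs. A
    two-component binomial mixture fitted by Expectation-Maximization
    separates true relationships (rejections caused only by genotyping
    error) from non-relationships. From verified parent-offspring pairs the
    package estimates a lower bound and an allele-frequency-adjusted
    per-genotype error rate, flags SNPs with recurrent Mendelian
    inconsistencies, detects duplicated samples by genotype concordance,
    and computes the number of SNPs required to resolve relationships at a
    given power. A pedigree and genotype simulator with known truth
    (crossbred designs, miscalls, duplicates, systematically failing SNPs)
    supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
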