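Package: hlassoc
Title: Case-Control Association Analysis of HLA Class II Alleles and
    Extended Haplotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control immunogenetics of the HLA class II
    region. Parses WHO-nomenclature allele names (including non-amplified
    DRB3/DRB4/DRB5 "null" calls and merged allele groups arising from
    mixed typing resolutions), reconstructs extended
    DRB3/4/5-DRB1-DQA1-DQB1 haplotypes by inheritance within nuclear
    families and by anchor-haplotype assembly in unrelated subjects, and
    builds allele, haplotype and genotype frequency tables with
    cross-product odds ratios, Woolf confidence intervals, Pearson
    chi-square and Fisher exact tests. Implements the relative
    predispositional effects (RPE) sequential-elimination procedure,
    conditional second-haplotype analyses among risk-haplotype carriers,
    and a seeded synthetic cohort generator (linkage-disequilibrium
    structured haplotype pool, Hardy-Weinberg sampling, nuclear-family
    transmission, risk-based case ascertainment) with recorded
    ground-truth phase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
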