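Package: slcohap
Title: Star-Allele Haplotype and OATP1B1 Phenotype Analysis for SLCO1B1 Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort analysis of the two functional SLCO1B1 variants
    c.388A>G (rs2306283) and c.521T>C (rs4149056): per-ancestry-group minor
    allele frequencies, exact Hardy-Weinberg testing, EM estimation of the
    *1a/*1b/*5/*15 star-allele haplotype frequencies from unphased genotypes,
    CPIC-rule diplotype to OATP1B1 transport-phenotype classification, and
    cross-group contingency testing. Includes a reproducible multi-group
    cohort simulator (random mating with optional inbreeding) that emits
    VCF plus sample metadata with known haplotype-frequency truth, and
    utilities to reconstruct integer counts from published percentage tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
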