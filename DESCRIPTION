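Package: proxyrvat
Title: Rare-Variant Aggregation Testing with a Family-History Proxy Phenotype
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene- and set-level rare-variant aggregation analysis against an
    age-weighted family-history (GWAS-by-proxy) phenotype for late-onset
    dementia. Implements the pseudo-linear proxy score built from own and
    parental diagnoses, functional variant masks (LOFTEE-style pLOF classes,
    REVEL-thresholded missense, synonymous control), cumulative-allele-frequency
    gene filtering, SKAT-O with beta(1,25) minor-allele-frequency weights and
    mixture-of-chi-square tail probabilities, single-variant scans, genomic
    inflation, Bonferroni and BH-FDR decisions, sensitivity and conditional
    reruns, pooled gene-set tests, and a synthetic exome-plus-family-history
    cohort generator with Mendelian transmission so the whole pipeline runs
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
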