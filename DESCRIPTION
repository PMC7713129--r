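Package: dgvar
Title: Deleterious Germline Variant Calling and Germline-Somatic
    Interaction Analysis in Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A filter-cascade framework for identifying putative
    deleterious germline variants (pDGVs) in cancer cohorts from annotated
    germline variant calls, together with its downstream analyses:
    case-control burden enrichment of pDGVs against rare synonymous
    variants (allele-count Fisher tests), purity-corrected loss of
    heterozygosity calling across serial tumors, multi-caller somatic
    consensus filtering, and gene- and pathway-level germline-somatic
    interaction detection via hypergeometric over-representation. Includes
    a fully seeded synthetic-cohort generator with planted ground truth so
    every stage of the pipeline can be exercised and calibrated without
    access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    fgsea,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
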