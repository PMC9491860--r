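Package: scnareg
Title: Proteogenomic Analysis of Gene Dosage Compensation and Regulation
    under Somatic Copy-Number Alteration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies RNA-level and protein-level compensation of gene
    dosage changes in tumor proteogenomic data. Computes per-gene, per-sample
    log2 fold changes relative to a copy-number-neutral reference, a
    compensation score with bootstrap median inference, per-gene DNA-RNA and
    RNA-protein Spearman correlation profiles with pathway-level aggregation,
    arm-count aneuploidy scores from copy-number segments, covariate-adjusted
    linear models relating expression to aneuploidy, and preranked gene-set
    enrichment over the resulting t-value ranking. Ships a synthetic
    proteogenomic data generator with known ground truth so every stage can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
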