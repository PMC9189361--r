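Package: methylmorph
Title: Promoter Methylation Calling, Tumor Morphometry and Stage-Wise
    Association Analysis for Myeloma Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studies linking microRNA promoter
    hypermethylation to target-gene overexpression in multiple myeloma.
    Implements amplicon bisulfite-sequencing analysis (CpG site and island
    detection, in-silico bisulfite conversion, bisulfite-aware global
    alignment, per-site C/T methylation calls and region methylation rates),
    binary-mask tumor-shape regularity scoring (maximum Feret axis, minimum
    enclosing circle, F-value) with the caliper volume formula, intrahepatic
    invasion-depth ratios from section masks, and the stage-wise statistical
    layer (per-stage linear regressions, group comparisons with Bonferroni
    correction, and a power-based sample-size check). Seeded synthetic-data
    generators provide promoter sequences, bisulfite read sets, tumor and
    liver-section masks, and stage-structured cohorts so every stage of the
    pipeline is testable without patient or animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
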