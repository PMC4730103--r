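Package: ewcer
Title: Expression-Weighted Cell-Type Enrichment from Single-Cell References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a gene list has higher cell-type-specific
    expression than expected by chance, using a specificity matrix derived
    from an annotated single-cell RNA-seq reference and a bootstrap null of
    random gene lists drawn from a background gene universe. Supports
    transcript-length and GC-content matched (decile-grid controlled)
    sampling to remove known gene-property biases, a transcriptome mode
    that tests the extreme tails of a differential-expression ranking, and
    consensus merging of bootstrap evidence across independent studies.
    Includes a synthetic-data generator with planted cell-type marker
    structure so every stage can be exercised with known ground truth.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
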