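Package: noisescreen
Title: Protein Function Screening from Natural Cell-to-Cell Variability in
    Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a correlation screen that infers candidate phenotype
    genes from the natural cell-to-cell variability of tagged proteins in
    time-lapse microscopy. From tracked single-cell tables it computes
    protein features (total fluorescence, gray-level co-occurrence contrast
    and texture correlation) and motility features (velocity, turning-angle
    change, aspect ratio), pools cells and frames per protein, correlates
    every protein/motility feature pair with Pearson and Spearman statistics,
    calibrates significance with a within-field-of-view trace-permutation
    null, estimates false discovery rates, calls candidates with a dual
    correlation threshold and a per-field robustness filter, and tests
    annotation enrichment with exact hypergeometric tail probabilities. A
    synthetic-data generator reproduces the statistical structure the screen
    relies on (persistent cell individuality, protein-motility coupling,
    field-of-view batch effects) with known ground truth.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
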