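Package: popweave
Title: Dasymetric Population Mapping with Land-Cover and Climate-Zone Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Redistributes administrative-unit census counts onto a fine grid
    using land-cover density weights stratified by climate zone, in the style
    of the AsiaPop/WorldPop family of gridded population products. Includes
    the areal-weighting (GPW-style) and urban-concentration (GRUMP-style)
    baseline methods, nonnegative least-squares estimation of per-zone
    per-class density weights from fine-scale census countries, urban/rural
    compound growth projection, national-total adjustment, and an
    aggregation-based accuracy-assessment framework (RMSE, %RMSE, MAE,
    correlation, Kruskal-Wallis with post-hoc pairwise rank comparisons).
    A seeded synthetic-landscape generator provides fully reproducible
    fixtures with known ground-truth weights.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
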