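Package: fbgeo
Title: Geostatistics and Environmental Drivers of the Soil Fungal:Bacterial Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping and explaining the soil fungal:bacterial (F:B)
    ratio across territorial-scale soil monitoring grids. Calibrates raw
    multi-plate 16S/18S rDNA qPCR data to absolute copy densities with the
    master-curve method, fits Matern variogram models by maximum likelihood,
    interpolates by ordinary kriging with local neighbourhoods and evaluates
    models by leave-one-out cross-validation, partitions variance among soil,
    land-management, climate and spatial predictor groups by partial
    redundancy analysis with permutation tests, and contrasts land uses with
    tie-corrected Kruskal-Wallis tests and Bonferroni-adjusted post hoc
    comparisons. Includes a synthetic monitoring-network generator with known
    ground truth so every pipeline stage has a recovery test.
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
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
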