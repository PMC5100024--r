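Package: nscpheno
Title: Phenotyping Strategies for Rice Stem Non-Structural Carbohydrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing phenotyping experiments on stem
    non-structural carbohydrates (NSC) in rice. Provides synthetic-data
    generators for genotypes, replicated phenotypes and FT-NIR-like spectra; a
    Bayesian hierarchical model with a genomic relationship matrix for variance
    components, narrow- and broad-sense heritability, genomic estimated
    breeding values, line dispersion and genetic/environmental correlations; a
    replicate-size subsampling design study; a complete near-infrared
    calibration workflow (standard normal variate, Savitzky-Golay derivatives,
    Kennard-Stone partitioning, PLS-1/PLS-2 with full cross-validation and
    outlier screening); and stem-carbohydrate trait utilities such as the TNC
    remobilization index and multivariate contrast selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
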