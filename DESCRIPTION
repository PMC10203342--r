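Package: greenheat
Title: Urban Population Exposure to Land Surface Temperature Extremes and
    Greening Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying urban population exposure to land
    surface temperature (LST) extremes from gridded city rasters and for
    evaluating counterfactual urban-greening interventions. Exposure is
    measured in person-days as warm-season exceedances of a percentile LST
    threshold multiplied by resident population. Exceedance counts are
    modelled with a spatial lag model (maximum likelihood, concentrated
    likelihood over the autoregressive parameter) on vegetation (NDVI) and
    inverse-square distance-to-water predictors over k-nearest-neighbour
    row-standardized spatial weights. A scenario engine compares uniform
    NDVI increments against increments targeted at the most populated
    pixels, solving for the targeted increment that matches a reference
    exposure reduction and reporting the vegetation savings. A synthetic
    city generator provides spatially autocorrelated inputs with a known
    generating process so the full pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
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
    utils,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
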