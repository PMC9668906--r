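Package: monomict
Title: One-Dimensional Thermal and Ecosystem Simulation of Monomictic Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the seasonal thermal stratification, winter turnover,
    and pelagic biogeochemistry of a deep monomictic lake in a one-dimensional
    vertical water column. The physical submodel solves surface heat exchange,
    wind-driven vertical diffusion, and convective adjustment on a layered
    grid; the ecosystem submodel tracks phytoplankton, zooplankton, dissolved
    inorganic nitrogen and phosphorus, dissolved oxygen, and particulate
    organic carbon, with particle sinking and a sediment pool that consumes
    oxygen and releases nutrients. Includes a synthetic meteorological and
    nutrient-loading scenario generator, turnover-timing detection from
    surface and bottom series, model validation metrics, random-forest
    variable-importance analysis of turnover drivers, and linear regressions
    linking bottom-water hypoxia to phosphorus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
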