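Package: lurkit
Title: Land Use Regression Modelling of Ambient Ozone from Buffer-Based
    Geospatial Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building land use regression (LUR) exposure models for
    ambient ozone: multi-radius circular-buffer extraction of point, line,
    polygon and raster predictors around monitoring sites; temporal aggregation
    of daily measurements with completeness filtering; supervised
    sign-constrained forward variable selection gated on coefficient p-values
    and variance inflation factors; site-grouped k-fold cross-validation and
    temporal external validation; prediction of gridded concentration surfaces;
    and a synthetic-scene generator with planted ground truth for end-to-end
    verification of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
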