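Package: dispeer
Title: Distance- and Connectivity-Informed Penalized Regression for Brain
    Region Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Regularized linear regression for scalar outcomes with brain
    region predictors, where the penalty is a weighted combination of a
    structural-connectivity graph Laplacian, a spatial-proximity graph
    Laplacian, and a ridge term. Penalty weights are estimated by maximizing
    the marginal likelihood of the equivalent linear mixed model. Includes
    construction of distance-kernel proximity matrices and normalized graph
    Laplacians, a synthetic-data simulation framework with relative mean
    squared error and bias-variance summaries, and bootstrap-based
    confidence intervals and p-values for the penalized coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
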