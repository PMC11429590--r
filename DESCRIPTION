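Package: segjoint
Title: Joint Segregation Analysis of Major Gene Plus Polygene Mixed Inheritance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits major-gene-plus-polygene mixed inheritance models to
    multi-generation phenotype data from a six-generation cross design
    (P1, P2, F1, F2, BC1P1, BC1P2) by joint maximum likelihood over finite
    normal mixtures, selects among 24 genetic models by AIC, tests model
    adequacy with uniformity, Cramer-von Mises and Kolmogorov statistics on
    probability-integral-transformed residuals, and estimates first-order
    genetic effects and second-order variance components and heritabilities.
    Includes a forward simulator of six-generation phenotypes under any
    registry model for power studies and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
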