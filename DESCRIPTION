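Package: raydemog
Title: Demographic Analysis of Data-Sparse Devil Rays and Other Chondrichthyans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating the demography of data-poor elasmobranchs
    from length-at-age samples. Fits the three-parameter von Bertalanffy
    growth function by Bayesian posterior sampling under informative priors
    built from maximum size and size at birth; estimates total mortality Z
    from age-composition data by peak-truncated catch-curve regression with
    a delete-a-fraction bootstrap; derives fishing mortality F = Z - M; and
    computes the maximum intrinsic rate of population increase (r_max) by
    solving a juvenile-mortality-corrected Euler-Lotka equation with Monte
    Carlo propagation of life-history uncertainty. Includes simulators for
    length-at-age data and fished age structures so every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
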