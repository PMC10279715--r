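Package: ssfmix
Title: Free-Path Statistics for Photon Transport in Binary Isotropic-Poisson Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Exact single-step function (free-path probability density) for
    photon transport in a binary isotropic-Poisson statistical mixture.
    Provides the jump-count probability mass function, the Bessel-form
    alternating-tessel path-length densities, the mixture single-step
    function with its distribution function, mean, quantile look-up table
    and effective albedo, the fixed-start (equilibrium) step law, and the
    direct Monte Carlo simulators that validate the analytic results, so a
    random binary medium can be replaced by one equivalent homogeneous
    medium in Monte Carlo light-propagation codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
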