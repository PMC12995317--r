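Package: blockspin
Title: Block Spin Ising Models and Community Detection from Binary Traits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the block spin Ising model (multi-group Curie-Weiss
    model) of dependent binary observations: exact simulation through the
    group-sum sufficient statistic, mean-field free-energy landscape analysis
    with asymptotic pair-correlation limits in the high- and low-temperature
    regimes, large-deviations failure-probability bounds, and the iterative
    correlation-window clustering algorithm that reconstructs the latent group
    partition of a population from a sample of +/-1 configurations. Includes
    independent reference computations (brute-force enumeration, de Finetti
    quadrature, Sanov-type bounds) for validation, file formats for samples
    and model configurations, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
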