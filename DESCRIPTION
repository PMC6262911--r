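Package: knockoutr
Title: Knockout Extinction Models for Bipartite Mutualistic Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates coextinction cascades in bipartite ecological networks
    (typically plant-pollinator communities). Implements a suite of knockout
    extinction models -- Secondary Only, Deterministic Avalanche, and Random
    Walk -- in binary and weighted form under a fractional loss threshold,
    together with robustness distributions, extinction-rank statistics,
    threshold sweeps, degree-distribution null models, structural metrics
    (connectance, NODF nestedness, degree skewness), a synthetic network
    generator, and a command-line interface for reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
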