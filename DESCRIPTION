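Package: rpspulse
Title: Cyclic Three-Species Ecosystems Under a Transient Death-Rate Pulse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Simulates a rock-paper-scissors (May-Leonard) ecosystem of three
    cyclically interacting species in which one species suffers a
    finite-duration elevation of its death rate. Provides a lattice
    Monte-Carlo engine with von Neumann neighbourhoods and periodic
    boundaries, a discrete-time stochastic rate-equation engine with
    pluggable reproduction-rate noise, classification of long-time outcomes,
    survival-probability maps over the pulse-strength/pulse-duration plane,
    cross-engine pulse-scale comparison, and least-squares estimation of the
    early-pulse Malthusian decay rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
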