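Package: signalsim
Title: Spatially Explicit Agent-Based Simulation of Animal Signalling
    Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates signalers and receivers on a continuous toroidal
    landscape to compare the information content of contrasting
    signalling systems. Signalers display whenever their energy budget
    allows, optionally requiring an external display item; receivers
    rank signalers under lek versus sequential assessment and cumulative
    versus real-time observation. Provides tie-corrected Kendall's
    coefficient of concordance between true display effort and receiver
    estimates, full-factorial sweeps over the eight model builds and
    resource abundances, and a general linear model of concordance on
    the design factors with partial eta-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
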