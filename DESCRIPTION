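Package: adspn
Title: Stochastic Petri Net Models of Neuronal Pathways in Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An extended stochastic Petri net (SPN) engine with standard,
    inhibitor, read and equal arc semantics, an exact Gillespie-style
    stochastic simulation algorithm with seeded ensembles, and an independent
    continuous-time Markov chain oracle based on uniformization of the
    reachability graph. Ships declarative SPN models of four neuronal
    signalling networks implicated in Alzheimer's disease (calcium influx and
    efflux channels, the Calpain-Calpastatin regulatory system, amyloid
    precursor protein processing, and their crosstalk), together with
    therapeutic-intervention variants, trace metrics (first-passage onset
    times, species dominance, calcium homeostasis diagnostics, oscillation
    summaries, depletion fractions), synthetic fixture nets with closed-form
    behaviour, and PNML import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Matrix,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
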