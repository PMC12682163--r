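Package: paapcea
Title: Decision-Tree Cost-Effectiveness Modelling of Penicillin Allergy
    Assessment Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing a
    primary-care initiated penicillin allergy assessment pathway (PAAP)
    with usual care over a five-year horizon. Implements a decision tree
    for first-year testing, de-labelling and treatment-failure outcomes,
    regression-based extrapolation of annual costs to later years with a
    constant-QALY assumption, probabilistic sensitivity analysis with
    Beta/Lognormal method-of-moments parameter distributions, Markov-chain
    relabelling scenarios, subgroup analysis, and value-of-information
    analysis (EVPI, per-parameter EVPPI, EVSI, expected net benefit of
    sampling). A synthetic two-arm trial generator with administrative
    censoring supports parameter estimation from individual-level data
    and end-to-end testing without access to trial records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
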