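Package: pharmsd
Title: System Dynamics Simulation of Sustainable Drug Supply Chains in Hospital Pharmacies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A stock-and-flow system dynamics toolkit for modelling the
    sustainability of the drug supply chain in hospital inpatient pharmacies.
    Provides a fixed-step forward-Euler integrator with the standard system
    dynamics primitives (first-order smooths, material delays, non-negative
    stocks), a signed causal-loop-diagram analyzer with feedback-loop
    enumeration and reinforcing/balancing polarity classification, a concrete
    pharmacy supply-chain model covering medicine expiration, disposal waste,
    inter-pharmacy transfers, resident over-prescription and pharmacy
    profitability, a seeded synthetic parameter generator emulating a
    multi-pharmacy survey, policy scenario analysis with baseline comparison
    reports, and the classical model validation tests (structure verification,
    parameter verification, boundary adequacy, trend-pattern classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
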