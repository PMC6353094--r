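Package: endopain
Title: Cost-Effectiveness Modelling of Oral Contraceptives for Endometriosis-Related Pain
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state monthly Markov cohort model comparing combined oral
    contraceptives against no hormonal treatment (analgesics only) for
    endometriosis-related pain, from an NHS perspective. Health states are
    defined by the numerical rating scale for pain (no pain, mild, moderate,
    severe, plus all-cause mortality). The package provides the cohort engine
    with half-cycle correction and discounting, cost and QALY accrual,
    incremental cost-effectiveness analysis with dominance classification,
    a one-way sensitivity analysis excluding GP consultations, probabilistic
    sensitivity analysis with Beta/Dirichlet/Gamma parameter uncertainty,
    cost-effectiveness plane and acceptability curves, the expert-elicitation
    computations (Beta/Dirichlet fits to hypothetical-patient transition
    counts, roulette "chips and bins" histogram fits), a microsimulation
    oracle for validating the cohort engine, and synthetic-data generators
    for every model input.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
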