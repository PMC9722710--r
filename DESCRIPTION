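Package: ddiburden
Title: Markov Cohort Model of Unintended-Pregnancy Burden from
    Contraceptive Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state absorbing Markov cohort model that quantifies the
    number and direct medical cost of unintended pregnancies attributable to
    pharmacokinetic drug-drug interactions between oral contraceptives and
    enzyme-inducing co-medications, from a United States payer perspective.
    Annual contraceptive failure rates (Pearl index) are converted to monthly
    transition probabilities via a constant-hazard transform, a closed cohort
    is traced over a one-year horizon, and expected outcome counts (birth,
    induced abortion, spontaneous abortion, ectopic pregnancy) are costed
    with median/minimum/maximum unit costs, including a discounted
    mistimed-birth adjustment. Includes deterministic interval propagation
    for incremental burden between strategies, scenario transformations
    (typical-use failure rates, abortion-share shifts, age-specific outcome
    mixes), and an individual-level stochastic microsimulation that serves as
    an independent convergence oracle for the deterministic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
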