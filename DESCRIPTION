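Package: hivcea
Title: Lifetime Markov Microsimulation Cost-Utility Analysis of First-Line
    Antiretroviral Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-level semiannual Markov microsimulation comparing
    first-line lopinavir/ritonavir against two atazanavir/ritonavir
    strategies in treatment-naive HIV-infected adults, over eight health
    states defined by CD4 cell count and viral-load detectability. Includes
    calibration of full row-stochastic transition matrices from published
    self-transition probabilities, event risks (AIDS, coronary heart
    disease, opportunistic infections, chronic kidney disease, treatment
    adverse events), line switching, life-table mortality with an HIV
    mortality-rate-ratio, discounted cost and QALY accrual, a deterministic
    cohort-level oracle for verification, and a full probabilistic
    sensitivity analysis with ICER-plane classification and
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
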