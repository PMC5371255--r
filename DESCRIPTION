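Package: taskshiftCBA
Title: Cost-Benefit Analysis of Task-Shifted Alcohol-Reduction CBT for
    HIV+ Outpatients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Societal-perspective cost-benefit model of rolling out
    task-shifted group cognitive-behavioral therapy (CBT) to reduce
    alcohol use among HIV-positive outpatients in Kenya. Provides
    ingredient-based cost ledgers for counselor training and per-site
    scale-up, two monetized benefit streams (averted HIV treatment
    costs from lowered alcohol-attributable incidence; labor-force and
    household productivity gains mediated by antiretroviral adherence),
    end-of-year discounting, benefit-to-cost ratios, one-way (tornado)
    sensitivity analysis, Monte Carlo probabilistic sensitivity
    analysis, and an individual-level microsimulation oracle for the
    cohort closed forms.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
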