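Package: fibscreen
Title: Cost-Utility and Budget-Impact Modelling of Liver Fibrosis Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree plus Markov cohort model for evaluating one-time
    screening strategies for significant liver fibrosis (stage F2 or higher)
    in adults with metabolic syndrome or obesity, from a societal perspective.
    Implements a screening cascade (FIB-4 or SAFE triage followed by transient
    elastography, or elastography alone) with imperfect test accuracy, a
    13-state lifetime Markov model of MASLD natural history with age-dependent
    mortality and lifestyle-intervention effects, incremental cost-effectiveness
    analysis with simple and extended dominance, one-way and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, threshold
    analysis on the elastography unit cost, and a five-year open-cohort budget
    impact analysis. A synthetic-data module generates life tables and toy
    scenarios with closed-form solutions so the full pipeline runs and is
    testable without any external data.
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
    optparse
Config/testthat/edition: 3
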