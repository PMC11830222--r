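Package: ndisineq
Title: Causal Analysis of Social Inequalities in Disability-Scheme
    Eligibility, Plan Allocation, and Spending
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying social inequalities in a national
    individualised disability-support scheme: synthetic unit-record
    generation with a known-truth causal structure, cohort construction
    with auditable exclusion logs, Monte Carlo simulation-based
    g-computation of total causal effects (eligibility per 1000
    applications; plan size and spending in annualised dollars), and
    decomposition of spending inequalities into interventional direct and
    indirect effects with plan size as mediator, with percentile
    bootstrap confidence intervals throughout.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
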