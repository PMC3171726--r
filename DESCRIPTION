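Package: strokecoi
Title: Incidence-Based Lifetime Cost-of-Illness Modelling for Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state Markov cohort model of the natural history of
    stroke for incidence-based cost-of-illness analysis. Derives age- and
    gender-specific transition probabilities from national epidemiologic
    parameter tables (prevalence, first-ever incidence, attack rate,
    one-year survival, background mortality with a standardized mortality
    ratio), runs yearly-cycle cohort simulations to estimate post-stroke
    life expectancy, years of life lost and expected lifetime costs,
    assembles per-person annual costs from micro-costing rules (uninsured
    fractions, informal caregiving, transport, productivity losses under
    human-capital and friction-cost valuation), projects the national
    lifetime burden from incident case counts, and runs one-way sensitivity
    analyses. Includes an internally consistent synthetic-data generator
    and a Monte-Carlo microsimulation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
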