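Package: injuryburden
Title: Burden of Conflict-Related Intentional Injury from Household Survey Data
Version: 0.1.0
Authors@R:
    person("Burden", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes disability-adjusted life years (DALYs) lost to
    conflict-related intentional injuries from record-level household-survey
    data, decomposed into incidence-based years of life lost (YLLs) and years
    lived with disability (YLDs). Provides a standard (aspirational) reference
    life table and country-specific alternatives, a disability-weight registry
    with beta-distributed draw-level uncertainty, classification of injuries
    into short-term, long-term recovered, and permanent patterns with treated
    and untreated variants, incidence- and prevalence-based YLD allocation,
    bootstrap uncertainty intervals, cause-specific decomposition, population
    extrapolation, and a synthetic household-survey generator so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
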