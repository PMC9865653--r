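Package: sodiumCKD
Title: Proportional Multistate Lifetable Modelling of Sodium Reduction and
    Chronic Kidney Disease Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the long-term impact of population sodium-reduction
    policies on chronic kidney disease (CKD) burden and healthcare costs using
    a proportional multistate lifetable (PMSLT). Sodium scenarios are converted
    into systolic blood pressure shifts with separate effects for hypertensive
    and normotensive subpopulations, translated into potential impact fractions
    on CKD incidence via the distribution-shift method, and propagated through
    four cause-specific illness-death Markov submodels (hypertensive,
    diabetic, glomerulonephritic and other/unspecified CKD) coupled to
    age-sex cohort lifetables. Outputs include incident cases and deaths
    averted, health-adjusted life years gained with a by-cause decomposition,
    and discounted healthcare-cost offsets, with probabilistic sensitivity
    analysis. A synthetic-data generator produces internally consistent
    stratified inputs emulating Australian national data sources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
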