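Package: stratquota
Title: Stratified Quota Sampling Frames, Site Allocation and
    Representativeness Assessment for Hard-to-Reach Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, running and auditing stratified
    quota-sampling recruitment of hard-to-reach populations.  Builds
    census-anchored sampling frames (age band by gender by socioeconomic
    status), converts census proportions into integer strata targets by
    largest-remainder (Hamilton) apportionment, randomly allocates
    recruitment quotas to community sites under eligibility constraints
    with residual allocation to public spaces, monitors recruitment
    progress and survey attrition, analyses researcher-organisation
    engagement (contact tallies, referral networks, Welch two-sample
    comparisons), and assesses representativeness of the achieved sample
    against a census profile (strata percentages, signed differences,
    population-pyramid data, categorical marginals).  A seeded
    synthetic-community generator lets the whole pipeline run end-to-end
    with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
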