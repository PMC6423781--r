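Package: msap
Title: Multi-Component Sexual Activity Profile Classification for School Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies members of a school-based cohort as sexually active by
    combining self-report with five biological and behavioural indicators (HIV
    serostatus, HSV-2 serostatus, urine pregnancy test, prior pregnancy or
    having made someone pregnant, and an STI symptom screen), the
    multi-component sexual activity profile (MSAP). Provides staged attribution
    and mutually exclusive indicator-combination decompositions of the students
    newly identified beyond self-report, participant flow-diagram summaries,
    prevalence estimation with cluster (school) level summaries suitable for
    cluster-randomised designs, two-sample t-tests on cluster summaries, risk
    perception cross-tabulations, a synthetic cohort generator with latent
    activity and partial-disclosure structure, and a deterministic fixture
    cohort reconstructed from published marginal counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
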