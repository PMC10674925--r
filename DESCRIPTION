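Package: adheretraj
Title: Longitudinal Medication-Adherence Trajectories from Dispensing Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates continuous medication availability (CMA9) from pharmacy
    dispensing records with supply carryover and end-period exclusion, clusters
    12-month adherence trajectories with longitudinal k-means selected by the
    Calinski-Harabasz criterion, profiles trajectory groups (age-adjusted
    Charlson comorbidity index, polypharmacy, persistence, switching to other
    heart-failure drug classes), and models group membership with multinomial
    logistic regression and stepwise covariate selection. Includes a seeded
    synthetic-cohort generator emulating the mixture structure of a
    sacubitril/valsartan incident-user cohort so the whole pipeline runs
    without access to the source claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
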