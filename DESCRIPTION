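Package: abcost
Title: Decision-Analytic Cost-of-Illness Modelling of Induced Abortion in Uganda
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-tree cost-of-illness model of induced abortion in
    Uganda. The model follows a cohort of abortion seekers through provider
    choice (trained vs. untrained), procedure failure and retry, post-abortion
    complications, access to hospital or out-patient care, and mortality, and
    accounts every dollar into direct medical, direct non-medical and indirect
    (productivity) categories as well as patient and government payer views.
    Premature mortality is valued by the human-capital approach with
    discounting. Includes Monte Carlo probabilistic sensitivity analysis with
    beta distributions for probabilities and normal distributions for costs,
    one-way (tornado) sensitivity analysis, national scale-up, and a synthetic
    study generator with analytic ground truth for validating the engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
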