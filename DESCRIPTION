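Package: iaqscreen
Title: Screening Indoor Air Quality with Surrogate Pollutants and Updatable Likelihood Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening unsatisfactory indoor air quality (IAQ) in
    air-conditioned offices from three surrogate pollutants (carbon dioxide,
    respirable suspended particulates and total volatile organic compounds).
    Implements the fractional-dose IAQ index, nine-pollutant assessment against
    named exposure-limit schemes, a seeded synthetic-survey generator with
    truncated log-normal marginals and a Gaussian copula, a cross-validated
    grid-search comparison harness over nine classifiers, and a Monte-Carlo
    procedure that updates the screening likelihood-ratio table when an
    exposure standard is tightened.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
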