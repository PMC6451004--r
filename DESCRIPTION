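Package: funcresp
Title: Functional-Response Inference for Prey-Depletion Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of prey-depletion functional
    responses from predator-prey feeding trials: the Rogers
    random-predator (type II) equation solved with the Lambert-W function
    and a flexible type II/III generalization whose attack rate scales as
    a power law of initial prey density. Includes control-based
    correction of initial densities, polynomial logistic shape
    diagnostics, AICc model comparison, nonparametric bootstrap
    confidence intervals and fitted-curve bands, difference-parameterized
    cross-treatment comparisons, nematode biomass and ingestion
    accounting, and a synthetic trial generator with a mechanistic
    stochastic foraging simulator. Tidy interfaces throughout: tibbles in
    and out, broom-style tidy() and glance() methods, and ggplot2
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
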