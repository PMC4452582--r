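Package: dinobloom
Title: Plankton Community Dynamics of Parasite-Controlled Dinoflagellate Blooms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an eight-state plankton community model coupling
    nutrient-limited phytoplankton growth, infection of dinoflagellate hosts by
    a syndinean parasite with explicit free-living infective stages
    (dinospores), and two microzooplankton grazer guilds (microciliates and
    rotifers). Provides scenario generators for community-complexity and
    nutrient-forcing experiments, exact decomposition of the model right-hand
    side into named flux terms for cause-of-death attribution during bloom
    demise, component-removal effect intensities, and variance-based (Sobol')
    global sensitivity analysis with Saltelli cross-sampling. Results are tidy
    tibbles with broom-style tidy()/glance() methods and ggplot2 autoplot()
    methods.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
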