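Package: proteocost
Title: Cost-Benefit Allocation of Chaperone Holdases and Foldases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a biophysical cost-benefit model of cellular
    proteostasis. Foldases (ATP-consuming chaperones such as HSP70) are
    modelled with Michaelis-Menten steady-state kinetics, holdases
    (ATP-independent small heat-shock proteins) with a binding
    equilibrium, and chaperone expression is optimized so that a fixed
    unfolded-protein exposure is met at minimum ATP cost. Provides the
    equilibrium solvers and their limiting-case approximations, ATP cost
    accounting (synthesis and running costs, breakeven times), a
    constrained allocation optimizer swept across synthesis rates,
    log-log allometric scaling fits of chaperone abundance against
    metabolic or synthesis rate, and seeded generators of synthetic
    abundance tables and aging trajectories for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
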