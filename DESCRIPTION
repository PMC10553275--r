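Package: ecoflow
Title: Eco-Evolutionary Dynamics of Resource Flow and Public Goods Cooperation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulation of an eco-evolutionary model in
    which individuals gather regenerating basal resources on a lattice or in a
    mixed population, play a public goods game, pay metabolic costs, reproduce
    by binary fission and mutate. Includes the closed-form equilibrium theory
    for perfectly mixed populations (Poisson-mixture expected payoffs, Lambert-W
    density branches, cooperation thresholds), the dynamical mean-field ODE with
    fixed-point stability analysis used to locate the onset of non-equilibrium
    fluctuations, and post-processing of simulation output into time-averaged
    densities, payoff and basal-resource accounting, birth rates and lifespan
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
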