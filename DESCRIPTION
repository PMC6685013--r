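Package: rootabc
Title: Likelihood-Free Inference for Stochastic Root Architecture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and likelihood-free (approximate Bayesian computation)
    inference for stochastic models of plant root system architecture. A hybrid
    stochastic-deterministic simulator grows a primary root under a linear or
    negative-exponential elongation law and places first-order lateral branches
    by a Poisson (Gillespie) process, a minimum-separation rule, or at fixed
    spacings along the primary. Observed or synthetic root systems are reduced
    to longitudinal summary statistics (branch count, primary root length, mean
    lateral root length) and compared to simulations through a scaled Euclidean
    distance. Rejection ABC and ABC sequential Monte Carlo with model selection
    recover posterior distributions over growth and branching parameters and
    over competing model structures. Includes synthetic-data presets emulating
    published Arabidopsis and Lupinus root-simulator parametrizations, readers
    for summary tables and RSML (Root System Markup Language) files, and
    weighted posterior summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    xml2,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
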