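Package: cbre
Title: Controlled Branching Processes with Infection Thinning in Random Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and exact analysis of population-size controlled
    branching processes evolving in an independent and identically
    distributed random environment, where each individual is additionally
    thinned by a Bernoulli infection indicator. Provides exact one-step
    transition laws by probability generating function convolution,
    conditional moment formulas, quenched distribution propagation,
    generating-function machinery for certain-extinction criteria and
    extinction-probability lower bounds, seeded Monte Carlo trajectory and
    ensemble simulation, and diagnostics for the supermartingale and
    submartingale normalizations of the process.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
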