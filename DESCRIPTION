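Package: immunalloc
Title: State-Dependent Allocation Between Immunocompetence and Offspring
    Production
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the life-history trade-off between a
    brooding or pregnant parent's investment in its own immunocompetence
    and its investment in offspring production.  Provides closed-form and
    brute-force solutions of the single-season (semelparous) optimum,
    backward-induction dynamic-programming solvers for deterministic and
    stochastic reserve gain over an iteroparous lifetime, seeded forward
    Monte Carlo simulation of populations following an optimal policy,
    and estimation of the emergent (realized) mortality rate from
    simulated survivor counts.  Preset experiments sweep the brooding
    fraction, background mortality and immune-efficacy parameters and
    export results as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
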