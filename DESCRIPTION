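Package: iwbsim
Title: Integrated Wellbeing Lifecycle Simulation and Allocation Optimisation
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling integrated wellbeing as a Cobb-Douglas
    composite of bounded domain indices, with discrete-time lifecycle
    dynamics for physical and financial wellbeing: logistic ageing decay,
    concave health investment, health-span and lifespan thresholds, labour
    and interest income under a no-borrowing budget, full-lifespan
    trajectory simulation under allocation policies, static and policy-grid
    allocation optimisers, and numerical verification of the model's
    comparative-statics propositions (option value of health spending,
    dominance of joint domain improvement, and the required-return gradient
    in physical wellbeing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
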