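Package: ipra
Title: Integrated Probabilistic Risk Assessment for Nanosilica in Food
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional (variability by uncertainty) Monte Carlo risk
    assessment of nanosilica (food additive E551) from dietary exposure.
    Implements probabilistic exposure assessment from 24-hour-recall
    consumption surveys with usual-intake (logistic-normal-normal) modelling,
    probabilistic hazard characterization via quantal benchmark-dose
    modelling with parametric-bootstrap model averaging and probabilistic
    extrapolation factors, margin-of-exposure (IMoE) risk characterization
    with uncertainty bars, and a 2^7 factorial decomposition of uncertainty
    contributions. Includes seeded synthetic-data generators emulating the
    survey and rat dose-response study designs, so the full pipeline is
    testable without access to the non-public source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
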