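Package: ikkdelay
Title: Mechanistic Models of Delayed IKKbeta Phosphorylation at Low IL-1 Doses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary differential equation models of IL-1 and UVB driven
    IKKbeta phosphorylation in epithelial cells, comparing a core
    receptor-driven model against three mechanisms that can delay kinase
    activation at low IL-1 doses: positive feedback (TRAF6-like
    auto-ubiquitination), sequential double phosphorylation, and an
    irreversible inhibitor. Provides chi-square fitting of western-blot-style
    time courses with per-dose observation scale factors, multi-start
    identifiability analysis, AICc model discrimination, dose-dependent
    relative sensitivity analysis, and a synthetic blot-data generator for
    recovery and discrimination studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
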