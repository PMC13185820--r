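Package: stabcouple
Title: Above- and Belowground Ecosystem Stability Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to upscale annual soil respiration from site records with a
    nonlinear stepwise regression on composite (PC1) environmental indices, to
    quantify temporal stability (mean/SD) of belowground and aboveground carbon
    fluxes over full periods and 10-year moving windows, to map the coupling
    between the two stability fields, and to attribute that coupling to
    productivity versus climate stability via random forests, partial
    correlations, variance partitioning, and structural equation models. A
    seeded synthetic gridded world with known generative coefficients makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
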