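Package: glidekin
Title: Gliding Motility Kinematics and Spiral Formation in Filamentous
    Cyanobacteria
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of gliding motility in
    filamentous cyanobacteria such as Phormidium. Implements the
    offset-exponential ("slime gun") post-reversal speed law, a fitting
    pipeline from tip-trajectory tables to reversal cycles and decay-law
    parameter estimates (terminal velocity, time constant), pooled speed
    distribution summaries and condition comparisons, a rule-based
    two-dimensional plate simulator in which sheath-trail guidance,
    counterclockwise curvature on virgin substrate and left turns at
    filament encounters give rise to supracellular spirals, and seeded
    synthetic-track generators that emulate time-lapse tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
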