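Package: iridoptics
Title: Transfer-Matrix Optics and Cell-Behavior Statistics for Zebrafish
    Iridophore Crystallotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo transfer-matrix simulation of reflectance from
    guanine reflecting-platelet stacks in zebrafish iridophores, with two
    built-in crystallotype presets (the ordered stripe type and the
    disordered interstripe type). Includes seeded synthetic generators for
    layer stacks and crystal morphometry, spectral summaries (peak, width,
    CIE 1931 chromaticity, stripe/interstripe contrast), an analytic
    quarter-wave model of the norepinephrine spacing response, and
    statistics for time-lapse iridophore behavior (axial division-plane
    orientation, migration bias, proliferation rates) driven by a seeded
    synthetic track generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
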