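Package: rsascreen
Title: Multi-Layer RNAi Screen Normalization, RSA Gene Ranking and Hit Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for arrayed siRNA reporter screens with dual
    readouts (pathway reporter plus viability/transfection channel). Provides
    plate-level quality control, viability-based well exclusion, ratio
    normalization, normalized percent inhibition (NPI), robust per-replicate
    z-scores, probability-based redundant siRNA activity (RSA) gene ranking
    with low-support filtering, multi-screen hit triage (validation call,
    counter-screen exclusion, dual-readout secondary-screen call, final
    intersection), and a seeded synthetic-screen generator with planted
    inhibitors, toxic and off-target siRNAs and plate artifacts for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
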