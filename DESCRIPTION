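Package: micutrace
Title: Contact Interval Reconstruction and Simulation for UWB Badge Proximity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing ultra-wideband (UWB) proximity-badge data
    collected from healthcare workers in an intensive care unit. Raw
    start/end contact records are reconstructed into clean, symmetric
    contact intervals, imputed into per-second contact histories with a
    deterministic in-room inference, and summarised as weighted contact
    graphs, room dwell times, transit times, and time-of-day badge counts.
    An agent-based simulator of badge-wearing staff in a medical intensive
    care unit emits format-identical synthetic raw records together with
    ground-truth contact episodes, so the whole pipeline can be exercised
    and validated without access to a real deployment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
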