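Package: hdmea
Title: Dual-Mode High-Density Microelectrode Array Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of dual-mode high-density microelectrode array (HD-MEA)
    recordings that sample a full-frame stream (all electrodes, lower
    signal-to-noise) simultaneously with a low-noise stream from a selectable
    electrode subset. Provides hexagonal electrode-array geometry and a
    chunked recording container, cross-mode spike-triggered averaging of
    electrical footprints, a backward-tracking algorithm for axonal arbors
    and conduction velocities, population-rate network-burst detection,
    cross-correlogram inference of putative monosynaptic connectivity with a
    convolution-null significance test, and a ground-truth recording
    simulator for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
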