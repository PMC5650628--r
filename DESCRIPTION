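Package: ccabci
Title: Covert-Attention BCI Decoding with Canonical Correlation Spatial
    Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decodes which of several peripheral objects a subject covertly
    attends from multichannel event-related EEG/MEG recordings.  Each object
    is flashed in a constrained pseudo-random sequence; the package encodes
    the sequences as binary impulse reference functions, jointly estimates
    spatial filters and matched-filter templates by canonical correlation
    analysis, and ranks candidate objects by their atanh-averaged
    correlations.  Ships the full evaluation harness (leave-one-run-out
    cross-validation, online simulation with incremental filter updates,
    cross-subject transfer learning, permutation-based chance estimation,
    Wolpaw information transfer rate, truncated-stimulation and
    channel-subset analyses) and a synthetic trial generator emulating
    oddball flash schedules, P300-like evoked responses, a stimulus-locked
    6 Hz oscillation and spatially correlated sensor noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    MASS,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
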