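Package: ibsync
Title: Real-Time Inter-Brain EEG Synchrony Engine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes inter-brain connectivity between two or more
    simultaneously recorded EEG streams (hyperscanning) over sliding
    windows of band-limited analytic signals. Implements six pairwise
    metrics (coherence, imaginary coherence, envelope correlation, power
    correlation, phase-locking value, circular correlation coefficient),
    electrode-pair averaging (one-to-one or all-to-all), per-band
    weighting, min-max normalization against manual and baseline-derived
    limits, and packed output frames suitable for neurofeedback sinks.
    Includes a synthetic multi-subject generator with controllable von
    Mises phase coupling and envelope correlation for ground-truth
    validation, plus offline and simulated-live session drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
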