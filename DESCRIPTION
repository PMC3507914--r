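Package: fpwatch
Title: Fasciculation Potential Surveillance with High-Density Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fasciculation potentials (FPs) in multi-channel
    high-density surface EMG recordings with a threshold-based spike
    detector and cross-channel consensus, computes order-i inter-FP
    intervals I(i) = t(n+i) - t(n), and constructs cumulative
    probability-of-observation curves that answer how long a relaxed
    muscle must be recorded before i FPs will have been observed with a
    given probability. Includes a renewal-process simulator that
    synthesizes ground-truth event trains and multi-channel recordings
    (8x8 electrode grid or 20-channel linear bar array) so the whole
    pipeline is testable without patient data, plus readers and writers
    for EDF and a lossless float32 binary layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
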