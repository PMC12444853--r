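Package: drgfilter
Title: Spike Propagation Failure Analysis for Dual-Site Nerve Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, sorts and matches extracellular spikes recorded
    simultaneously on a spinal nerve (pre-ganglion) and its dorsal root
    (post-ganglion), quantifying fiber-type-resolved spike propagation
    failure ("filtering") at the dorsal root ganglion T-junction.
    Includes MAD-threshold spike detection, Haar-wavelet waveform
    features with Gaussian-mixture unit clustering, minimum-latency
    matching of dorsal-root spikes to their spinal-nerve origin,
    A/C fiber classification by conduction velocity, epoch-based firing
    rate and force-regression analysis, and a ground-truth Poisson
    spike-train simulator for validating matching accuracy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    mclust,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
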