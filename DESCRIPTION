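Package: stomapolar
Title: Cortical Polarity Quantification and Lineage Dynamics for the
    Stomatal Lineage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative tools for studying asymmetric cell divisions in
    the Arabidopsis stomatal lineage from fluorescence microscopy. Samples
    cortical intensity profiles in 63 equal arc-length portions around
    traced cell outlines, fits a wrapped-Gaussian crescent model, and
    computes the polarity index (fraction of portions at or above half the
    per-cell maximum) together with crescent size and peak height. Measures
    post-division crescent persistence and normalized amplitude decay from
    time-lapse series, represents whole-leaf lineage-tracing records with
    division-type classification and tissue summaries (stomatal index,
    cell-number trajectories, meristemoid amplification histograms), and
    links the symmetric/asymmetric division balance to tissue composition
    through a stochastic branching simulator with an analytic
    stomatal-index oracle. A synthetic-data module renders ground-truthed
    two-channel cell images, time series and lineage records so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
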