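Package: howloc
Title: Acoustic Localisation of Howling Canids by Time-Difference-of-Arrival Multilateration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localising vocalising animals from arrays of
    GPS-synchronised autonomous recorders. Salient points marked on the
    spectrograms of three or more recorders give time differences of
    arrival (TDOAs); the source position is estimated by hyperbolic
    nonlinear least squares (coarse grid search followed by
    derivative-free refinement) in a local planar frame. Includes readers
    for deployment and salient-point tables (CSV and Raven-style
    selection tables), grouping of howls into events by silence gaps,
    classification of estimates against the local convex hull of the
    contributing recorders, accuracy and detection-distance summaries
    against known source positions, and a synthetic-survey generator
    (recorder arrays, sources, arrival-time jitter, distance-dependent
    detection) for testing array designs end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
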