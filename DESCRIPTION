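Package: ictalwave
Title: Spatiotemporal Analysis of Focal Epileptiform Activity in Widefield Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise how focal epileptiform events start and spread in
    widefield calcium-imaging movies of mouse visual cortex. Detects interictal events
    and seizures on a simultaneously recorded local field potential, fits the rank-1
    standing-wave model of event onsets, fits the multiplicative contiguity-by-homotopy
    model of the V1-to-LM activity profile, maps the delay to seizure invasion and its
    dependence on cortical and retinotopic distance from the focus, and analyses 6-11 Hz
    ictal oscillations with Hilbert-phase delay maps and spiral (pinwheel) detection.
    Includes a synthetic-cortex generator with planted, recoverable parameters that
    emulates the retinotopic organisation of V1 and LM, plus readers and writers for
    movies (multi-page TIFF + JSON sidecar), traces (CSV) and fit bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
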