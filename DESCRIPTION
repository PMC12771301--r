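Package: elascape
Title: Energy Landscape Analysis of Binarized Brain Activity States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits pairwise maximum-entropy (Ising) models to binarized
    multichannel time series such as region-of-interest (ROI) BOLD signals,
    and analyses the resulting energy landscape: exact Boltzmann
    probabilities over all 2^N activity states, local minima, basins of
    attraction, minimax energy barriers and disconnectivity trees. Includes
    temporal-dynamics summaries (occupancy, dwell episodes, non-self
    transitions), per-state two-group comparison with Bonferroni correction
    and signature-state selection, a synthetic two-group cohort generator
    with known ground-truth couplings, and an end-to-end pipeline with
    plain-text file interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
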