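Package: neurophys
Title: Feature Extraction for Patch-Clamp, Calcium Imaging and Enrichment
    Networks in Neuronal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell patch-clamp recordings and
    calcium-imaging time series from cultured human neurons, together with a
    gene-set enrichment network builder. Extracts evoked action-potential
    counts and rheobase-spike shape features (threshold, amplitude, width,
    fast afterhyperpolarization), capacitance-normalized sodium and fast/slow
    potassium currents from voltage-clamp step families, and spontaneous
    excitatory post-synaptic current statistics. Classifies calcium-imaging
    ROIs into active neurons, active astrocytes and inactive cells, and
    quantifies network synchrony by windowed pairwise correlations and a
    power-spectral-density band-area ratio. Ships a synthetic-data generator
    with exact ground truth so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    igraph,
    pracma,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
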