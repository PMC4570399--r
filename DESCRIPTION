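Package: spikegha
Title: Multi-Channel Spike Sorting with NEO Detection and Hebbian PCA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for online multi-channel extracellular spike sorting built
    around an incrementally trained principal-component model. Spikes are
    detected with the nonlinear energy operator (NEO), peak-aligned, and
    projected onto synaptic weight vectors learned by the generalized Hebbian
    algorithm (Sanger's rule), with both double-precision and emulated 17-bit
    fixed-point arithmetic backends. Includes a synthetic extracellular
    recording generator with ground truth, a cycle-accurate behavioural model
    of the shared-core streaming datapath with its closed-form channel-capacity
    bounds, fuzzy c-means clustering of feature vectors, and classification
    success rate scoring against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
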