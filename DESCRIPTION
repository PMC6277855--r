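Package: spiketype
Title: Semi-Supervised Classification of Cortical Neuron Types from
    Action-Potential Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies neocortical neuron subtypes (pyramidal cells and
    PV, SST, VIP, 5HT3a interneurons) from the waveform shape of action
    potentials in whole-cell patch-clamp voltage traces. Implements the
    full pipeline: zero-phase 50 Hz notch and moving-average denoising,
    threshold spike detection with fixed -1/+2 ms epochs, discrete cosine
    transform and action-potential morphometry features, correlation-matrix
    principal component analysis, per-class fuzzy c-means cluster centers,
    and a minimum-distance (nearest-centroid) classifier, together with
    scatter-matrix class-separability (J3), stratified cross-validation
    metrics, paired classifier comparison tests (Cochran's Q, McNemar,
    Bonferroni), and a seeded synthetic-data generator producing labeled
    traces with ground-truth spike markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
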