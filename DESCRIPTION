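Package: strainspeech
Title: Silent-Speech Word Recognition from Biaxial Strain-Gauge Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, classification and model introspection for
    silent-speech interfaces built on skin-mounted piezoresistive strain gauges.
    Provides a physics model of the gauge and its voltage-divider readout, a
    synthetic-data generator emulating eight-channel facial strain recordings,
    a preprocessing pipeline assembling 2x4xT spatiotemporal tensors, a 3D
    convolutional word classifier with cosine-similarity and SVM baselines,
    evaluation protocols (stratified k-fold cross-validation, learning curves,
    exhaustive channel ablation, transfer-learning adaptation, SNR), and
    explainability tools (relevance-weighted class activation maps, t-SNE
    feature embedding, silhouette scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
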