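Package: cestmix
Title: Spatial-Spectral Deep Learning for CEST MRI Glioma Segmentation and
    Genotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chemical exchange saturation transfer (CEST) MRI
    analysis built around a hybrid convolution/self-attention segmentation
    and classification network. Provides a multi-pool Lorentzian Z-spectrum
    phantom generator with Rician noise and B0-shift degradation operators,
    conventional MTRasym and multi-pool Lorentzian-fit quantification,
    shift-window patch extraction with crop-and-stitch aggregation, a
    from-scratch trainable encoder-decoder network whose encoder stages mix
    windowed multi-head self-attention with depthwise convolution through
    bi-directional channel/spatial gates, patient-level probability
    aggregation (probability mean and majority vote), and patient-level
    statistics (stratified bootstrap confidence intervals, exact paired
    Wilcoxon signed-rank tests, Holm-Bonferroni correction, coefficient of
    variation). A minimal NIfTI-1 reader/writer and a command-line interface
    bind the pieces into an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
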