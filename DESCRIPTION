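Package: vqheal
Title: Geometry-Invariant Anomaly Detection in 3D Volumes via Vector-Quantized Token Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Unsupervised lesion detection in 3D medical-style volumes that is
    robust to varying voxel sizes, fields of view and 90-degree rotations. A
    vector-quantized autoencoder with CoordConv-style whole-body coordinate
    channels compresses volumes into discrete latent tokens; an autoregressive
    transformer, conditioned via cross-attention on auxiliary-modality tokens
    summed with quantized spatial-location tokens, models the likelihood of
    healthy token sequences. At inference, low-likelihood tokens are resampled
    into an ensemble of "healed" reconstructions decoded with dropout, and a
    voxel-wise kernel density estimate scored at the observed intensity yields
    an anomaly map. Includes a seeded synthetic phantom generator, segmentation
    metrics (best-achievable DICE, AUPRC) and a pipeline command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
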