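Package: sctwin
Title: Synthetic CT from Cone-Beam CT with Shifted-Window Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Translates low-quality cone-beam CT (CBCT) slices into
    planning-CT-like synthetic CT using a U-shaped hierarchical
    encoder-decoder built from window and shifted-window multi-head
    self-attention blocks with locally enhanced feed-forward layers,
    trained with a composite Charbonnier plus multi-scale structural
    similarity objective under a Lookahead-wrapped Adam optimizer.
    Ships a seeded digital pelvis-phantom simulator (cupping,
    photon-starvation streaks, beam-hardening bands, noise, global HU
    shift), slice-wise volume inference, and a radiotherapy evaluation
    stack: HU-accuracy metrics (MAE, RMSE, PSNR), HU histograms and ROI
    statistics, contour agreement (Dice, mean distance to agreement),
    and global 3D gamma analysis of dose grids.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    EBImage,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
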