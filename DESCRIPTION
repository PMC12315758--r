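Package: mridenoise
Title: Resolution-Invariant Denoising of Structural Brain MRI with Nested
    Maxout Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for denoising structural brain magnetic-resonance volumes
    at arbitrary voxel sizes. Implements the conforming preprocessing pipeline
    (isotropic cubic resampling, RAS reorientation, clipped-histogram intensity
    rescaling), a Rician noise simulator with stationary and spatially variable
    sigma fields, a nested (UNet++-style) encoder-decoder denoiser with maxout
    feature competition, voxel-size-invariant latent resolution normalization
    and six lambda-weighted residual noise candidates, comparator architectures
    (plain encoder-decoder with resolution normalization, multi-channel DnCNN),
    perceptual image-similarity metrics (SSIM, MS-SSIM, deep-feature and
    LPIPS-style losses, PSNR, Dice/IOU), a one-cycle AdamW training harness,
    three-plane view-aggregated inference, synthetic multi-tissue head
    phantoms, and a command-line front end. The network forward and backward
    passes are computed by compiled kernels; no external deep-learning
    runtime is required.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
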