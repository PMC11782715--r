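Package: mrsiclean
Title: Water and Lipid Nuisance Signal Removal for Proton MR Spectroscopic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removal of residual water and subcutaneous-lipid nuisance signal from
    whole-brain 1H MR spectroscopic imaging (MRSI) spectra. Implements a dual-encoder
    1D convolutional network (Y-Net) that identifies the combined lipid+water signal
    from a spectrum and its lipid-subspace projection, together with the conventional
    baselines it is compared against: lipid L2-regularization via the subspace
    operator (1 + beta L L^H)^-1 with automatic beta calibration, and HLSVD water
    removal by damped-sinusoid (Hankel SVD) decomposition of the FID. A quantum
    spin-system simulator generates metabolite basis spectra from chemical shifts and
    J-couplings, and a parametric nuisance generator plus a k-space-truncation
    phantom provide fully synthetic training and evaluation data. Post-processing
    includes rank-truncated spatiotemporal denoising and range-restricted NRMSE,
    suppression-factor, SNR and FWHM metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
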