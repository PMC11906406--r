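Package: icoseg
Title: Icosahedral Group-Equivariant Convolutional Networks for Diffusion MRI Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Direct (regular-representation) group-equivariant convolutional
    networks for volumes of spherical signals, aimed at voxel-wise tissue
    segmentation of diffusion-weighted MRI. Implements the 60-element
    icosahedral rotation group with Cayley, inverse and coset (fiber)
    tables; Watson-kernel interpolation of per-voxel antipodally symmetric
    spherical signals; the three equivariant operators (S2 lifting
    convolution with a star-shaped kernel, SO(3) fiber group convolution,
    rotation-tied 3x3x3 spatial convolution) plus max-projection; an
    ablation family of architectures (classical CNN, SO(3) baseline,
    decoupled T3xSO(3), partial and full SE(3), rotation-averaged classical)
    with exact parameter accounting; seeded training with focal loss and
    octahedral rotation augmentation; evaluation metrics (per-class
    accuracy, Dice, overall accuracy) and rotated-test-set robustness
    protocols; and a synthetic diffusion-tensor phantom generator so every
    component is testable without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
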