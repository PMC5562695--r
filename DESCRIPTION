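Package: mserg
Title: Multi-Scale Spectral Embedding Registration for Multimodal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deformable co-registration of multimodal 2-D images (for example
    ex vivo histology against in vivo T2-weighted MRI) driven by multi-scale
    spectral embedding representations. Haralick co-occurrence and Gabor
    texture features are extracted at several length scales from the spatially
    concatenated image pair, reduced by independent component analysis, and
    spectrally embedded into a shared low-dimensional coordinate system whose
    vectors are far more alike across modalities than raw intensities. A
    k-nearest-neighbour entropic-graph alpha mutual information measure drives
    multi-resolution B-spline free-form registration over the combined scale
    channels. Includes an intensity mutual-information baseline, learning-set
    scale selection, Dice/RMSD/mean-deformation-difference evaluation metrics,
    thin-plate-spline landmark warping, and a seeded synthetic multimodal
    phantom generator with known ground-truth deformations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    RNifti,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
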