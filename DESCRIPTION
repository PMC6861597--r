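Package: segae
Title: Unsupervised Brain Tissue and White Matter Hyperintensity
    Segmentation with a Constrained Convolutional Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments brain tissues and white matter hyperintensities (WMH)
    from co-registered, skull-stripped multi-sequence MRI (FLAIR, T1-w,
    T2-w, optionally PD-w) without manual labels. A three-scale fully
    convolutional autoencoder produces soft material maps through a Softmax
    constrained by the brain mask, and reconstructs each MRI sequence as a
    non-negative weighted sum of those maps (linear unmixing). Training
    minimises a scale-invariant cosine loss with a Laplacian term and an
    anti-overlap activity regulariser, using Adam with Nesterov momentum.
    An iterative pure-tissue bias-correction loop, a synthetic phantom
    generator, sliding-window inference with post-processing, and the full
    lesion evaluation metric suite (Dice, H95, AVD, lesion-wise TPR/F1,
    volume correlation) make the method testable end to end without real
    MRI data.
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
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
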