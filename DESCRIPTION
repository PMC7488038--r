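Package: pituitexture
Title: Semi-Supervised Texture Grading of Pituitary Tumor MRI Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for grading the softness (texture) of pituitary tumors
    from unbalanced two-domain MRI slice sequences. Provides an unpaired
    cycle-consistent domain converter that synthesizes each patient's missing
    T1 or T2 sequence, a dense-block/residual-block autoencoder for
    unsupervised per-slice feature extraction, a convolutional-recurrent
    classifier trained with one label per patient, and a repeated-split
    evaluation protocol with paired Wilcoxon signed-rank arm comparisons.
    All networks run on a compact reverse-mode automatic differentiation
    engine with C++ convolution kernels. A synthetic two-domain phantom
    cohort generator with known ground truth makes every stage testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
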