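Package: cuplseg
Title: Semi-Supervised Polyp Segmentation with Consistency Training and
    Continuous Pseudo-Label Update
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Training framework for semi-supervised binary segmentation of
    colorectal polyps from endoscopic imagery. Implements a mean-teacher
    scheme in which the teacher network is the exponential moving average of
    the trained student, a transformation-consistent perturbation
    consistency loss over random scaling, Gaussian noise and right-angle
    rotation, and continuous update of pseudo-labels (CUPL): teacher-derived
    soft labels for unlabeled images are confidence-filtered by
    teacher-student disagreement, averaged with their previous round, and
    fed back into training. The segmentation network is a nested-skip
    encoder-decoder with channel-spatial attention and deep supervision,
    built on hand-written convolution kernels so the whole pipeline runs on
    a plain CPU. A synthetic polyp-like fixture generator makes every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
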