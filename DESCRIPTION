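Package: heSNN
Title: Privacy-Preserving Tumor Classification with a Shallow Neural Network
    over Simulated Homomorphic Encryption
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-label tumor-type classification from copy-number and
    somatic-mutation-effect data under an encrypted-inference protocol.
    Implements HE-friendly gene filtering (Hamming-distance clustering of
    copy-number columns and effect-mass thresholding of variant records), a
    shallow linear network trained in plaintext whose composed weight matrix is
    consumed by encrypted inference, a plaintext simulator of CKKS SIMD slot
    semantics with operation counters, the duplicated diagonal packing for
    encrypted matrix-vector products (including complex-pair packing and the
    rotate-and-sum circuit), and a polynomial softmax built from a scaled-limit
    exponential and Goldschmidt division. A synthetic-cohort generator makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'cohort-io.R'
    'he-sim.R'
    'metrics.R'
    'model-io.R'
    'packing.R'
    'preprocess.R'
    'softmax.R'
    'train.R'
    'pipeline.R'
    'synth.R'
    'utils-internal.R'
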