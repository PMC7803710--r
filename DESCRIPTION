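Package: CranioSeg
Title: Automated Craniofacial Bone Segmentation from Multi-Contrast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated segmentation and intensity-preserving 3D
    rendering of the craniofacial skeleton from magnetic resonance imaging.
    Implements two pipelines: a black-bone (gradient-echo) only algorithm,
    and a modified algorithm in which a bone mask segmented from a
    low-resolution zero-echo-time (ZTE) acquisition constrains the
    segmentation of high-resolution black-bone or FIESTA-C data, resolving
    the bone/air ambiguity intrinsic to black-bone contrast. Includes
    grid-aware volume containers, rigid mutual-information registration,
    physical-space morphology, a smooth multiplicative bias-field
    corrector, NIfTI and DICOM series input/output, STL surface export,
    and a parametric multi-contrast digital head phantom with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'CranioSeg-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'geometry.R'
    'morphology.R'
    'metrics.R'
    'registration.R'
    'io-nifti.R'
    'io-dicom.R'
    'mesh.R'
    'config.R'
    'preprocess.R'
    'segment.R'
    'phantom.R'
    'cli.R'
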