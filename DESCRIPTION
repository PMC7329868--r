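Package: ctseg
Title: CT-Specific Preprocessing, Augmentation and Segmentation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for robust convolutional segmentation of computed
    tomography (CT) volumes. Provides Hounsfield-unit aware preprocessing
    (percentile windowing, z-score normalisation, random slice sampling to a
    fixed stack size, in-plane downsampling), a CT-specific image augmentation
    (CTIA) operator suite including the cluster-wise voxel intensity range
    shift (CWVRS), a smoothed Tanimoto plus categorical crossentropy compound
    loss, 2D and 3D modified U-Net and mixed-scale dense (MS-D) network
    backbones trained with ADAM, slice-count-sorted cross-validation folds,
    and a stacked ensemble combining 3D binary localisers with 2D multi-class
    classifiers. Includes a synthetic HU-calibrated CT phantom generator so
    the whole pipeline is testable without clinical data, NIfTI input/output,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
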