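Package: slicefuse
Title: 2.5D RGB Slice Superposition for CT Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds 2.5D training images from abdominal CT by fusing three
    consecutive axial slice crops into the red, green, and blue channels of a
    single image, so that an ordinary 2D convolutional classifier can exploit
    inter-slice structure. Includes a minimal single-frame CT DICOM reader and
    writer, an ImageJ rectangle ROI parser, Hounsfield rescaling and display
    windowing, seeded geometric augmentation with minority-class balancing,
    patient-grouped k-fold cross-validation, a small reference convolutional
    network with Grad-CAM activation maps, pooled confusion-matrix metrics
    with Wilson intervals, ROC/AUC with the paired DeLong test, an integer
    confusion-matrix reconstruction oracle for published performance tables,
    and a synthetic lesion phantom generator in which class identity is
    carried only by the cross-slice drift of the lesion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
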