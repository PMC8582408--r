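Package: fractalDerm
Title: Surface Fractal Dimension and Color-Cluster Features for Skin
    Lesion Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and classification toolkit for dermoscopy
    and clinical skin-lesion images. Implements a two-dimensional Higuchi
    surface fractal dimension descriptor computed per RGB channel,
    percentage-of-color-area features over a configurable set of RGB
    color-cluster boxes, Welch t-test feature selection, and two
    classifiers (k-nearest neighbours under stratified 5-fold
    cross-validation, and a radial basis function neural network trained
    by greedy incremental centre selection) together with a
    confusion-matrix metric suite (sensitivity, accuracy, precision, AUC,
    Dice, MSE). Ships synthetic-data generators (fractional Brownian
    surfaces, lesions of exactly known colour composition, two-class
    Gaussian feature tables) so the whole pipeline is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'color.R'
    'cv.R'
    'evaluation.R'
    'higuchi.R'
    'io.R'
    'knn.R'
    'pipeline.R'
    'preprocess.R'
    'rbfnn.R'
    'selection.R'
    'show-methods.R'
    'synthetic.R'
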