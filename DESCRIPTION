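Package: rwensemble
Title: Random-Walker Ensemble Segmentation and Radiomic Feature
    Concordance for Lung Nodule CT
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seeded random-walker ensemble segmentation of lung nodules in
    CT slice stacks, extraction of 38 radiomic features (19 grey-level
    co-occurrence matrix features including convexity, 7 grey-level run
    length matrix features, and 12 first-order histogram features), and
    validation of extracted features against ground-truth segmentations via
    tie-aware Spearman rank concordance with strength banding and t tests.
    Includes a deterministic synthetic CT phantom generator emulating
    solid, juxta-vascular, and juxta-pleural nodule classes with analytic
    ground-truth masks, readers and writers for DICOM series, multi-page
    TIFF stacks, PNG masks and CSV feature tables, and a command-line
    interface orchestrating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    EBImage,
    tiff,
    png,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Segmentation, FeatureExtraction, Visualization
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'image_io.R'
    'concordance.R'
    'dicom.R'
    'intensity.R'
    'glcm.R'
    'glrlm.R'
    'features.R'
    'phantom.R'
    'random_walk.R'
    'rwe_segment.R'
    'pipeline.R'
    'rwensemble-package.R'
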