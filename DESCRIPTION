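Package: vacuoquant
Title: Automated Quantification of Lymphocyte Vacuolization in Blood Smear Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage deep learning pipeline for quantifying lymphocyte
    vacuolization in single-cell peripheral blood smear crops: a U-Net style
    convolutional segmenter produces cell and nucleus masks, the cytoplasm mask
    is formed by subtraction and used to black out everything but the cytoplasm,
    and a residual convolutional classifier with a 2-neuron softmax head scores
    each cell for vacuolization, with a probability threshold turning scores
    into per-smear vacuolization percentages. Includes a synthetic generator of
    Romanowsky-stained lymphocyte crops with pixel-perfect ground-truth masks,
    geometric data augmentation applied jointly to images and masks, Grad-CAM
    attribution maps, and method-comparison statistics (Passing-Bablok
    regression with bootstrap confidence intervals, Bland-Altman agreement
    analysis, Pearson correlation, and Levene's variance-homogeneity test).
    All networks train on a small self-contained CPU engine, so the full
    pipeline runs end-to-end on a single core.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'augment.R'
    'mask-ops.R'
    'unet.R'
    'nn-core.R'
    'seg-model.R'
    'resnet.R'
    'cls-model.R'
    'method-comparison.R'
    'pipeline.R'
    'synthetic.R'
    'io.R'
    'vacuoquant-package.R'
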