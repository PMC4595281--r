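Package: hemiscope
Title: Task Performance and Lateralized Brain Activation Analysis for Motor fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying task performance and lateralized brain
    activation in block-design motor fMRI studies of hemiparesis. Implements
    data-glove kinematics (movement counting, envelope-boxcar compliance
    correlation, overt mirror-movement scoring), surface-EMG processing
    (scanner-artifact notch filtering, rectification, band-pass filtering,
    normalization to maximal voluntary extension, and the mirror-contraction
    score MM_EMG), proportional-threshold region-of-interest summaries of
    voxelwise activation maps with laterality indices and mid-sagittal
    hemisphere flipping, and the accompanying statistical layer
    (repeated-measures ANOVA, one-sample Wilcoxon tests against scale maxima,
    stepwise brain-behavior regression, and permutation-corrected voxelwise
    group t-maps). A synthetic-data generator produces glove traces, EMG,
    activation volumes, atlases and cohort tables with known ground truth so
    every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    RNifti,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'boxcar.R'
    'cohort.R'
    'emg.R'
    'glove.R'
    'hemiscope-package.R'
    'io.R'
    'pipeline.R'
    'roi.R'
    'simulate.R'
    'stats.R'
    'utils-signal.R'
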