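Package: ceusRadiomics
Title: Radiomic Analysis of Contrast-Enhanced Ultrasound Perfusion Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end radiomic analysis of destruction-replenishment
    contrast-enhanced ultrasound (CEUS) scans of tumours. Provides a
    ground-truthed synthetic phantom generator for three vascular
    phenotypes, wavelet (BayesShrink) speckle denoising, microbubble
    vessel segmentation with replenishment-kinetics fitting, extraction
    of a 235-feature radiomic vector (first-order, grey-level
    co-occurrence and run-length texture, vascular morphometry, and
    stationary-wavelet subband features), a four-criterion feature
    stability/discrimination ranking with correlation pruning to a
    four-feature signature, and cross-validated linear support vector
    machine classification with Wilson score confidence intervals, plus
    average-linkage clustering with exact multinomial enrichment tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, EBImage, e1071, minpack.lm,
    jsonlite, tiff, withr
Suggests: testthat (>= 3.0.0), mclust, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, ImageProcessing, Classification, Clustering,
    FeatureExtraction
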