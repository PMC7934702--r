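Package: radrobust
Title: Robustness Screening of Delta-Radiomics Features Against CT Acquisition Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether quantitative imaging (radiomics)
    features carry a biological signal that outweighs CT acquisition noise.
    The package extracts delta-radiomics features (tumor mass, sigmoid
    boundary offset, Gabor filter energy, wavelet detail energy, size) from
    lesion volumes and masks, screens features for test-retest
    reproducibility with Lin's concordance correlation coefficient, removes
    redundancy by Spearman-correlation hierarchical clustering with
    univariate AUC representatives, and classifies each surviving feature as
    robust or not per pair of scanning conditions by comparing cross-group
    biological-signal distributions against phantom-derived noise-signal
    distributions with pooled two-sample t-tests. A synthetic-data module
    generates phantom lesion images under controlled tube-current conditions
    and cohort/retest/phantom feature tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
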