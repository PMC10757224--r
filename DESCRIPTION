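Package: basketpca
Title: Tensorial Principal Component Analysis of Longitudinal Purchase Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing longitudinal grocery-purchase tensors
    (customers x product groups x weeks). Supports assembly of labelled
    purchase tensors from long-format transaction records, cohort exclusion
    filters and annual expenditure rescaling, mode-wise (tensorial) principal
    component analysis based on modal covariance matrices, augmentation-based
    selection of the number of components per mode, peeling of atypical weeks
    and product groups, score-based customer stratification and profiling,
    comparison with standard PCA on matricized data, and a synthetic
    loyalty-card data generator with known separable latent structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
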