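Package: ihcscore
Title: Computer-Aided Quantification of Chemokine-Receptor IHC in Tissue-Microarray Cores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative scoring of brightfield immunohistochemistry (IHC)
    images of tissue-microarray cores, together with the downstream cohort
    statistics used in biomarker prognosis studies. Implements Beer-Lambert
    colour deconvolution of hematoxylin/DAB stains, classical nuclei
    segmentation with cytoplasm-ring construction, per-cell compartment
    scoring against a single global DAB cut-off, percent-positive summaries
    per tissue region (glandular versus interstitial), and the accompanying
    statistical program: paired nuclear-versus-cytoplasm comparisons,
    clinicopathological group tests, logistic regression with ROC AUC, and
    Cox proportional-hazards survival models. A synthetic-data generator
    produces stained-core images with per-cell ground truth and patient
    cohorts with known effect sizes, so the whole pipeline is testable
    end-to-end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    survival,
    stats,
    utils,
    yaml,
    png,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    pROC,
    jsonlite
Config/testthat/edition: 3
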