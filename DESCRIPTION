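Package: budphase
Title: Transcriptome-Based Staging of Tree Flower Bud Dormancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-course flower bud transcriptomes in
    temperate fruit trees. Computes TPM and applies expression filters,
    clusters differentially expressed genes on Pearson-correlation distance,
    selects a minimal marker-gene panel by centroid correlation, tests
    transcription-factor target, promoter motif and GO term over-representation,
    and fits a cross-validated multinomial logistic regression on a
    two-dimensional PCA projection to classify the five bud dormancy stages
    (organogenesis, paradormancy, endodormancy, dormancy release,
    ecodormancy), transferable from RNA-seq to reference-normalized RT-qPCR
    data. Includes dormancy-release estimation from forcing-test bud-break
    series, relative standard-curve RT-qPCR quantification, and a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
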