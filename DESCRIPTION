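Package: specswath
Title: Classify Raw Mass-Spectrometry Runs from Binned Spectrum Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts centroided LC-MS/MS runs (mzML/mzXML) into fixed-width
    normalized intensity matrices by summing peak intensities inside equal
    m/z windows ("feature swath extraction"), trains a small feed-forward
    neural network to classify individual scans, and issues per-sample
    verdicts through a leave-one-out cross-prediction protocol with
    scan-level majority voting. Reports precision, recall, F1, cohort
    accuracy and ROC/AUC, and ships a deterministic synthetic DDA-run
    generator so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    mzR,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
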