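Package: omicsalign
Title: Sample-Identity Alignment and Label-Error Correction Across Multi-Omics Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, classifies, and corrects sample-labeling errors (swaps and
    mislabelings) between pairs of omics profile matrices using intrinsic
    biological cis-associations as per-sample barcodes. Implements a rank-based
    reciprocal matcher and a probabilistic matcher that scores candidate
    profile pairs with Mahalanobis p-values under a bivariate-normal model of
    similarity scores, iterated with cis-association re-estimation until
    convergence. Includes annotation-driven candidate pair construction
    (eQTL-style proximity windows, nearest-TSS assignment, explicit maps),
    preprocessing filters, a patient-centric view for localizing the data type
    carrying an error, and a simulation framework for power and accuracy
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
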