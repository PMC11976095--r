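Package: molardiff
Title: Rule-Based NLP Scoring of Mandibular Third Molar Extraction Difficulty from CBCT Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the surgical difficulty of mandibular third molar
    extraction from free-text cone-beam computed tomography (CBCT) radiology
    reports. A synonym-dictionary ("concept") matcher extracts four anatomical
    features per report -- tooth angulation, number of roots, root curvature,
    and relationship to the mandibular canal -- each mapped to an ordinal
    score; the total score classifies the case into four difficulty classes
    (D1 easy to D4 very difficult). A small feed-forward neural network learns
    the same mapping from extracted features. Includes a seeded synthetic
    report generator with gold labels, multiclass evaluation (confusion
    matrices, precision/recall/F1) and a three-way error taxonomy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
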