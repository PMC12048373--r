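Package: nodulematch
Title: Landmark-Based Registration and Longitudinal Matching of Pulmonary Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking pulmonary nodules across serial chest CT
    examinations from coordinate-level detections alone. Co-registers two
    exams by fitting an affine transform to anatomical landmark point sets
    with a trimmed iterative-closest-point solver, pairs nodules in the
    co-registered space under a Euclidean distance threshold with one-to-one
    greedy assignment, classifies per-lesion outcomes (correct match, missed
    matching, incorrect assignment, false-positive detection) against ground
    truth, and evaluates matching rates stratified by nodule localization
    and per-exam nodule count with chi-square contingency analysis, Pearson
    residuals, and Mann-Whitney tests. A synthetic-thorax simulator generates
    paired-exam studies with known truth (stylized lung geometry, landmark
    occlusion, diaphragm displacement, detection dropout, false-positive
    injection) so the full pipeline is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
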