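Package: topicgru
Title: Topic-Biased Recurrent Networks for Hospital Readmission Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-visit 30-day hospital readmission from longitudinal
    electronic health record (EHR) code sequences with a hybrid model that
    combines a gated recurrent unit (GRU) over visits (local context) with a
    per-patient Gaussian context vector inferred by a variational recognition
    network (global context). Includes corpus input/output for visit-sequence
    data, label construction from admission timestamps, a plain GRU ablation,
    repeated-run evaluation (ROC-AUC, PR-AUC, accuracy), patient embedding and
    k-means phenotype clustering, and two synthetic-EHR generators (a
    subsample-and-combine procedure over a source corpus and a de novo
    simulator with known ground-truth risk).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
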