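Package: ratda
Title: Colour-Block Image Encoding of Clinical Data for Rheumatoid
    Arthritis Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes a patient's hand-joint findings and clinical and
    laboratory data as a single two-dimensional colour-block image using
    semi-quantitative discretization rules, and classifies the resulting
    images as rheumatoid arthritis (RA) or nonRA. Provides domain types
    and tabular serialization for patient records, a deterministic
    image renderer and decoder with configurable layout and palette, a
    seeded synthetic-cohort generator matched to published class
    summaries, diagnosis-preserving data augmentation, a best-of-five
    training harness around a small convolutional network, and
    evaluation utilities (confusion matrix, precision/recall, Cohen's
    kappa, ablation comparison, and single-field counterfactual probes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
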