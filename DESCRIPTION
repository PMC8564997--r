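Package: platealign
Title: Reference-Point Registration Accuracy for Plate-Mounted Dental Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seeded in-silico evaluation of reference-point distributions for
    three-dimensional reconstruction of the intercuspal jaw relation from
    separately scanned maxillary and mandibular dental models. Simulates
    mounting plates carrying hemispherical concave landmarks, contact-probe
    "standard" measurements and optical-scan point clouds; extracts concave
    centers by two-stage least-squares sphere fitting; registers each jaw to
    the contact-measured standard by equal-weight landmark (Kabsch) alignment
    for seven reference-point groups; and quantifies trueness and precision of
    held-out inter-jaw distances (ISO 5725-1 style RMSE), with one-way
    ANOVA/Tukey comparisons across groups and two-way intraclass correlation
    reliability reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
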