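Package: cafcoculture
Title: Analysis Pipeline for CAF-Cancer Cell Coculture Studies in Head
    and Neck Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable implementations of the computational steps of a
    head and neck squamous cell carcinoma (HNSCC) cancer-associated
    fibroblast (CAF) coculture study: prototype mRNA-subtype
    classification of tumours from standardised marker-gene expression,
    colony-forming-assay image registration, blue-channel segmentation
    and area-fraction quantification, Hertz-Sneddon fitting of atomic
    force microscopy force-distance curves, real-time deformability
    cytometry event gating, comparative-Ct (delta-delta-Ct) relative
    expression, exact r x c Fisher contingency tests, lactate-shuttle
    gene clustering, and Kaplan-Meier / stepwise Cox survival analysis.
    A synthetic-data generator with planted ground truth emulates every
    input the pipeline consumes so all stages are testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    graphics,
    jsonlite,
    png,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
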