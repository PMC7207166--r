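Package: icdhallmarks
Title: High-Content Quantification of Immunogenic Cell Death Hallmarks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for image-based immunogenic cell death
    (ICD) screening: synthetic multi-channel fluorescence fields with planted
    ground truth, nuclear/cytoplasmic segmentation and per-cell measurement,
    anchored inhibition percentages for transcription (EU) and translation
    (AHA) assays, top-hat dot quantification of calreticulin translocation,
    single-cell HMGB1 nuclear release kinetics, surface overlap coefficients
    for nucleolar colocalization, four-parameter log-logistic dose-response
    fitting with IC60 estimation, RUSH secretion-assay inhibition and
    reversibility statistics, and compound-level integration (z-scores,
    Pearson correlations with declared exclusions, hit gating against a
    reference compound, Kolmogorov-Smirnov class enrichment).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
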