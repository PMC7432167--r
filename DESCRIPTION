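Package: reactAD
Title: Applicability Domains for Quantitative Reaction-Property Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for defining, tuning and benchmarking applicability domains
    (AD) of regression models that predict quantitative characteristics of
    chemical reactions (rate and equilibrium constants). Reactions are encoded
    as Condensed Graphs of Reaction (CGR) built from atom-mapped reaction
    SMILES; reaction types are recognised through canonical reaction-centre
    signatures; descriptors combine ISIDA-style fragment counts on the CGR
    with solvent, temperature and mixture-composition descriptors. Eleven AD
    definition methods (leverage, nearest-neighbour distance, one-class SVM,
    two-class Y-outlier classifier, bounding box, fragment control, reaction
    type control, random-forest ensemble variance, Gaussian-process predictive
    variance, and zero/perfect baselines) share a single fit/predict contract,
    are scored by coverage, OIR, OD, delta-R2 and AUC metrics, and are tuned
    and compared through a nested cross-validation benchmark with a penalty
    ranking scheme. A seeded synthetic reaction generator provides controlled
    reaction types, planted Y-outliers and non-native type injections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    kernlab,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
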