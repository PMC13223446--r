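Package: roughmri
Title: Rough-Set Neural Networks and Anti-Homomorphic Filtering for
    Multi-Focal Brain MR Lesion Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-domain enhancement of low-contrast, multi-focal
    hypoxic-ischemic-encephalopathy (HIE) lesions in neonatal brain MR
    slices, and classification of lesion stage.  Provides a homomorphic
    filter and its anti-homomorphic dual, rough-set attribute reduction
    (a local-redundancy stability measure over classical equivalence
    classes, and a neighborhood rough-set reduction driven by conditional
    information entropy), feedforward neural networks with paired
    lower/upper interval ("rough") weights initialised from boundary-region
    fractions, population metaheuristics (particle swarm, pelican, and
    hippopotamus optimisers) for weight tuning, conjugate-gradient,
    Levenberg-Marquardt and reduced-memory Levenberg-Marquardt training
    functions, a seeded synthetic phantom generator with partial-volume,
    chemical-shift and motion-ghosting artifacts, and a full evaluation
    suite (confusion counts, enhancement metrics, stage reports, pipeline
    orchestration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
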