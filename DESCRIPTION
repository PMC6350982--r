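Package: PlateSynergy
Title: Plate-Based Drug Combination Screening and Synergy Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of cell-based high-throughput drug-combination screens.
    Normalizes raw 384-well fluorescence reads to control-anchored HTS scores,
    computes the Z'-factor screening-window coefficient, and calls hit
    combinations against a plate noise floor. Quantifies synergy for
    constant-ratio combination designs by the Chou-Talalay median-effect /
    combination-index method, with sequential-deletion confidence intervals,
    dose-reduction indices, weighted combination indices and symbol grading,
    isobologram and Fa-CI plot data. Includes the Webb fractional-product
    classification for fixed-concentration designs, well-level high-content
    metrics from per-nucleus intensity tables, a synthetic-data generator with
    known ground truth for end-to-end validation, and a four-stage pipeline
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'wells.R'
    'io.R'
    'simulate.R'
    'scoring.R'
    'medianEffect.R'
    'combination.R'
    'webb.R'
    'hca.R'
    'pipeline.R'
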