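Package: socage
Title: Social Aging Analysis for Longitudinal Primate Behavioral Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study social aging in longitudinal behavioral
    observation data from group-living primates. Derives social-network
    metrics (degree, strength, dyadic sociality indices) from event-level
    focal observation records, computes pedigree kinship and kin
    availability, decomposes age effects into within-individual change
    versus between-individual differences via within-subject centering,
    tests for selective disappearance with the Model A / Model B contrast,
    and tests partner-selectivity predictions with dyadic partner-choice
    models. Ships a synthetic-cohort generator with known ground truth
    (including an explicit selective-disappearance mechanism) so the whole
    pipeline is testable end-to-end, plus parameter-recovery and
    confounding-separation experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
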