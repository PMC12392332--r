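Package: fgrscreen
Title: Birth-Weight-Correlated Biomarker Screening for a Mild Fetal
    Growth Restriction Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the statistical pipeline of a cerebrospinal-fluid
    (CSF) proteomic biomarker screen in a rat model of mild fetal growth
    restriction (FGR): classification of pups by a -1.5 SD birth-weight
    threshold, a per-protein Spearman correlation screen against birth
    weight with Storey q-values, dual-day significance and direction
    concordance, brain-expression filtering of candidates, Steel-Dwass
    all-pairs and Wilcoxon signed-rank group comparisons, densitometry
    and immunofluorescence normalization rules, and behavioral scoring
    indices (negative-geotaxis climb-up score, Y-maze spontaneous
    alternation, novel-object recognition, rota-rod learning). Includes
    seeded synthetic-data generators that emulate the cohort, the
    TMT-style CSF abundance matrices with planted birth-weight
    responders, longitudinal biomarker measurements and behavioral
    outcomes, so the whole pipeline is testable without the original
    deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
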