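Package: asescreen
Title: Scoring and Classification for RNAi Screens of ASE Neuron Fate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the complete phenotype scoring, hit-calling and
    multi-tier classification procedure of a genome-wide RNAi screen for
    the specification of the left/right asymmetric ASE gustatory neurons
    (ASEL/ASER) in Caenorhabditis elegans. Provides well-level scoring of
    the primary ASEL reporter screen with replicate-threshold positive
    calling, scoring of the secondary ASER/bilateral-ASE and tissue-marker
    screens, a deterministic rule cascade that assigns genes to phenotypic
    classes (early arrest, broad neuronal defect, ASE lineage defect, loss
    of ASE fate, left/right asymmetry classes I/II/IV), a synthetic screen
    generator with known ground truth for validating every stage, screen
    overlap and severity-shift comparisons, and the whole-genome-sequencing
    candidate-variant filter used for mutant cloning by mapping-interval
    background subtraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
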