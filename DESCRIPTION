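Package: gpcrstate
Title: Activation-State Metrics, Toggle-Switch Classification and
    Contact Scores for GPCR Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structural metrics for G protein-coupled receptor (GPCR)
    activation analysis, developed around cannabinoid receptor 1 (CB1):
    named inter-residue distance indicators of the active and inactive
    states, classification of the F3.36/W6.48 "twin toggle switch"
    side-chain configuration from chi1/chi2 dihedrals and residue
    positions, residue-residue contact scores (RRCS) and |delta RRCS|
    ranking across receptors, per-helix 7x7 RMSD matrices between
    activation states, and a P-I-F connector-motif scan.  Includes a
    deterministic synthetic seven-helix-bundle generator that emulates
    active and inactive receptor geometries and noisy interpolating
    frame series with known ground truth, so every stage of the
    analysis is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
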