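Package: betaridge
Title: Beta-Strand Residue Pairing from Predicted Contact Maps via Ridge
    Detection and Stacked Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies residue pairing in interacting beta-strands from any
    predicted residue contact map. The map is treated as a 2D image:
    gamma-normalized scale-space ridge detection extracts per-cell ridge
    height, direction, distance and width, and a three-stage random-forest
    framework combines ridge features with the raw map, secondary-structure
    probabilities, positional and map-level features to refine beta-beta
    contact predictions. Includes residue- and strand-level evaluation,
    CASP-RR-style distance-restraint export for contact-assisted folding,
    and a seeded synthetic contact-map generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
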