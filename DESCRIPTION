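Package: aaoscan
Title: Screening, Active-Site Typing and Comparative Analysis of
    Aryl-Alcohol Oxidase Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining aryl-alcohol oxidase (AAO) candidates from
    protein sequence sets: PROSITE-style signature parsing and scanning
    (PS00623, PS00624 and the ADP-binding fingerprint of the GMC
    oxidoreductase superfamily), homology-hit filtering, reference-anchored
    active-site typing of fungal, bacterial and arthropod sequences into
    kingdom-specific types, sequence-logo information content,
    neighbor-joining phylogenies with monophyly assessment, and Kabsch
    C-alpha superposition of structures.  Includes a seeded synthetic-data
    generator that plants all conserved AAO features with known ground
    truth, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
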