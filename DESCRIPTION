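Package: pdlkit
Title: Design and Analysis of Doped Phage-Displayed Peptide Libraries for
    Dual-Receptor Agonist Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational backbone of a doped ("soft
    randomized") phage-display campaign aimed at dual-receptor peptide
    agonists. Provides closed-form library statistics (mutation-class
    distribution, theoretical diversity, Poisson coverage, unique-clone and
    duplication estimates), trimer-codon degenerate oligonucleotide design
    with exact restriction-site probability via a sequence automaton and a
    deterministic codon optimizer, a seed-deterministic biopanning simulator
    for alternating two-receptor selection, mutation calling of selected
    clones against a parent backbone, and two-receptor EC50 potency and
    balance classification including DPP-IV liability detection and
    peptide-engineering transformations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
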