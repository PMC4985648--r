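Package: orloss
Title: Lineage-Specific Loss of Olfactory Receptor Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference chain for detecting lineage-specific loss of olfactory
    receptor (OR) genes from nucleotide sequences: identification of
    full-length intact OR coding sequences, extraction of one-to-one ortholog
    groups from support-annotated gene trees, codon-aware pseudogene calling
    (premature stop codons and frameshifting indels relative to an intact
    ortholog reference), Dollo-style placement of shared disruptions on a
    species tree, and an exact contingency test contrasting pseudogene
    fractions between lineage groups. A sequence-evolution simulator with
    planted, branch-specific disruptions provides ground truth for every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
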