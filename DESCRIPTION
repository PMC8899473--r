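Package: turripep
Title: Venom Peptide Libraries in a Phylogenetic Framework for Turrid Snails
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates turrid venom-peptide libraries with transcriptome-based
    phylogenetics. Builds a housekeeping-gene (HKG) panel shared across
    venom-gland transcriptome samples, infers per-gene neighbor-joining trees
    and a bipartition-frequency consensus species tree with gene-tree support
    fractions, classifies P-like turripeptides by cysteine framework and clade,
    normalizes toxin expression against the HKG mean, and tests
    genus-exclusivity of peptide clades with a permutation null. Ships a
    packaged table of predicted mature P-like turripeptide sequences from
    Turris and Purpuraturris species, plus synthetic-data generators so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
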