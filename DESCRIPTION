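Package: prolampep
Title: Multi-Enzyme In Silico Digestion and Epitope Mapping for Prolamin
    Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-table-driven in silico proteolytic digestion of cereal
    prolamin (gluten) proteins with six proteases (trypsin, low-specificity
    chymotrypsin, pepsin pH 1.3, thermolysin, LysC, proteinase K) applied
    singly, simultaneously and in two-step sequential workflows, with full
    parent lineage of every digestion event.  Annotates the resulting
    peptides with average, monoisotopic and singly-protonated monoisotopic
    masses, maps linear T- and B-cell epitopes onto proteins and digestion
    peptides by exact (100 percent identity) substring search, and exposes a
    cross-linked protein/peptide/epitope datastore with chained column
    filtering, mass search, peptide specificity summaries, grouped peptide
    count matrices and normalized epitope density.  Includes a seeded
    generator of prolamin-like synthetic fixtures with a ground-truth
    manifest, and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    BiocGenerics,
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
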