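Package: ltmap
Title: Rational Design and Assay Reduction for Amphipathic Antimicrobial
    Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the rational design of amphipathic alpha-helical
    antimicrobial peptide analogs, built around the latarcin-3a scaffold and
    its Lt-MAP analogs. Computes the standard physicochemical descriptor set
    (net charge, Fauchere-Pliska mean hydrophobicity, hydrophobic-residue
    percentage, Eisenberg hydrophobic moment) and helical-wheel projections;
    calculates average and monoisotopic peptide masses with singly charged
    b/y fragment ion ladders and matches them against observed MALDI peak
    lists; enumerates substitution-constrained analog candidates under a
    composition-divergence cap and ranks them by charge and amphipathicity
    objectives; and reduces broth-microdilution, crystal-violet biofilm,
    hemolysis and resazurin viability plate data to MIC, MBC, MBIC,
    percent-hemolysis, percent-viability and four-parameter logistic EC50
    endpoints. Seeded synthetic-plate and synthetic-spectrum generators make
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
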