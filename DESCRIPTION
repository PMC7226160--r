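Package: m5uevo
Title: Evolution of C5-Uracil Methyltransferase Repertoires in Mollicutes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for the C5-uracil (m5U)
    methyltransferase families of the Mollicutes. Classifies TrmFO-related
    proteins into the TrmFO, RlmFO and TrmFO-like subfamilies from diagnostic
    catalytic residues, cofactor-binding motifs and gene-neighbourhood
    conservation; reconstructs most-parsimonious gain/loss/duplication/
    pseudogenization/transfer scenarios for each gene family on a rooted
    species tree (Dollo and Sankoff parsimony, with an exact
    transfer-augmented Dollo search); checks genotype-phenotype consistency
    against empirical RNA-modification data; and simulates gene-content
    evolution and planted-signature protein sequences for validation.
    Ships a curated 39-species mollicute reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
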