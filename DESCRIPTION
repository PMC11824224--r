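Package: psmascreen
Title: Reverse Virtual Screening for Off-Targets of PSMA-Targeting Radioligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ligand-based reverse virtual screening (target fishing)
    of candidate off-target proteins of prostate-specific membrane antigen
    (PSMA) radioligands. Implements sequence-derived protein descriptors
    (amino-acid and dipeptide composition, autocorrelation, quasi-sequence
    order, amphiphilic pseudo amino-acid composition), 2D ligand descriptors,
    a PCA plus random-forest QSAR trained on protein-ligand binding free
    energies, quartile screening of protein libraries, salivary-gland
    expression filtering, and binding-pocket residue conservation scoring
    against FOLH1 by global pairwise alignment. Ships a synthetic-data
    generator emulating the statistical structure of docking/MD-derived
    binding-energy tables so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    randomForest,
    igraph,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
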