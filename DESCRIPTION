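Package: phosquant
Title: Label-Free Targeted Proteomics Quantification, Phosphosite
    Stoichiometry and Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for label-free parallel reaction
    monitoring (PRM) experiments: tryptic digestion and proteotypic peptide
    selection, fragment m/z computation and transition lists, simulation of
    extracted-ion chromatograms with known ground truth, baseline estimation
    and peak integration, relative protein abundance from summed fragment
    areas, phosphosite stoichiometry from paired phospho/nonphospho peptide
    forms, group statistics with compact letter displays, qPCR normalized
    relative quantities, and phosphosite conservation analysis (Jukes-Cantor
    distances, UPGMA trees with bootstrap support, BLOSUM62 window similarity,
    degenerate motif scanning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pracma,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
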