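Package: gc2struct
Title: Genomic GC-Content Bias in Amino-Acid Composition and Protein
    Secondary Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how the GC content of prokaryotic coding regions
    biases proteome amino-acid composition, Chou-Fasman conformational
    parameters, and three-state (helix/sheet/coil) secondary-structure
    composition. Provides coding-region GC and amino-acid frequency
    estimators, per-structure frequency and conformational-parameter
    tables, GC-trend regression with significance codes, orthologous-group
    (COG) representative filtering, bias calling and secondary-structure
    string alignment, plus a synthetic genome generator with known
    structure propensities for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
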