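Package: cogbias
Title: Composition-Bias Mining in Clusters of Orthologous Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines sequence-composition bias in clusters of orthologous
    groups (COGs): pooled frequency scores of amino acids, nucleotides and
    codons per COG or per user-defined COG group, under freely definable
    organism selections (by taxon, trait pattern or COG occurrence), with
    optional normalization against a whole-database or selection-wide
    reference and taxonomic subgrouping. Includes loaders for a NUCOCOG-style
    XML dialect and per-COG FASTA bundles, classic composition analyses
    (charged-residue ranking, cognate bias, thermophily proteome and codon
    signatures, GC content by oxygen requirement), a deterministic synthetic
    dataset generator with controllable biases, and a command-line interface.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    grDevices,
    graphics,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
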