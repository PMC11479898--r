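Package: LRlink
Title: Ligand-Receptor Communication Scoring Between Sender and Receiver
    Cell States
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers directed intercellular communication from bulk RNA-seq
    expression by scoring ligand-receptor pairs between a sender cell state
    (ligands restricted to differentially upregulated genes) and a receiver
    cell state. Expression is thresholded (FPKM > 1), scaled to [0, 10] by
    the mean of the top decile of expressed ligand or receptor values,
    multichain complexes are aggregated by geometric mean, and each pair is
    scored by the product of its scaled ligand and receptor levels. Includes
    a synthetic-data generator with planted active pairs for end-to-end
    validation and a chord-diagram renderer with a machine-readable
    geometry export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, Transcriptomics, Network, CellBiology, Software
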