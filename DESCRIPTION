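Package: embryoquant
Title: Single-Cell smFISH Quantification with Ground-Truthed Synthetic Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification pipeline for single-molecule FISH
    (smFISH) studies of transcription in early embryonic epithelia. Generates
    ground-truthed synthetic embryos (Voronoi cell lattice, telegraph-model
    bursty transcription per allele, nascent transcription sites, rendered
    multi-channel images), re-implements the imaging quantification steps
    (marker-controlled watershed cell segmentation, Laplacian-of-Gaussian spot
    detection, intron-probe transcription-site calling, spot-to-cell
    assignment), and provides the single-cell statistics used to compare
    genotypes: low-expression filtering, transcription-site subgrouping,
    neighbor-cluster dispersion (Fano factor and coefficient of variation),
    rank-based genotype comparison, and background-adjusted protein
    fluorescence. A canonical microRNA seed-site scanner (8mer, 7mer-m8,
    7mer-A1) over 3'UTR sequences is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
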