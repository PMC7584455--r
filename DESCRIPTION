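Package: tylandscape
Title: Ty LTR Retrotransposon Landscape Analysis for Yeast Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the genomic landscapes of Ty LTR
    retrotransposons in yeast lineages from processed sequencing
    derivatives. Includes intra-genome LTR sequence-similarity networks
    with percentile-based edge retention and family merging, estimation
    of evolutionary divergence since transposition, definition of
    cross-genome Ty orthogroups from whole-genome multiple-alignment
    coordinates, read-depth based copy-number estimation with
    control-gene flooring, declustering of non-reference insertion
    calls with allele frequency spectra and PCA, linear-model
    association of copy numbers with population structure and climate,
    selection-intensity and synonymous-diversity summaries, branching
    time extraction from ultrametric element phylogenies, and analysis
    of arsenite growth assays. A synthetic-data generator provides
    truth-known inputs with the statistical structure the analysis
    assumes, for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    lme4,
    lmerTest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    car
Config/testthat/edition: 3
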