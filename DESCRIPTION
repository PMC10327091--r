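Package: virolink
Title: Pairing Giant Viruses with Their Protist Hosts in Single-Cell
    Metatranscriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects actively infected protist cells in droplet single-cell
    metatranscriptomes of natural plankton communities and pairs giant viruses
    (Nucleocytoviricota) with their native hosts. Implements viral marker-gene
    UMI quantification with a three-criterion infected-cell call, per-cell
    greedy transcript assembly, thresholded best-hit 18S rRNA taxonomic
    assignment with conservative conflict omission, translated best-hit
    family profiling with link classification, a community embedding with
    infection overlay, and bloom-dynamics summaries. A synthetic-community
    generator with planted infection ground truth makes every stage testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    uwot
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    cluster
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, Metagenomics, Alignment, Virus
RoxygenNote: 7.3.3
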