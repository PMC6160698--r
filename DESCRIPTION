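Package: lncmetnet
Title: Metabolism-Associated lncRNA Coexpression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying and functionally annotating
    metabolism-associated long noncoding RNAs (lncRNAs) from paired
    tumor/normal expression microarrays. Implements quantile normalization,
    presence filtering and volcano-style differential expression on log2
    intensities; all-pairs Pearson coexpression networks with Fisher
    z-transform asymptotic p-values and Benjamini-Hochberg FDR edge
    selection; hub-based guilt-by-association Gene Ontology annotation of
    lncRNAs via hypergeometric enrichment of coexpressed protein-coding
    neighbors; integration of coexpression, protein-protein interaction and
    direction-filtered miRNA-target evidence into one typed network; and
    comparative threshold-cycle (2^-ddCq) quantification of qPCR data with
    clinicopathological association tables. A synthetic-data generator with
    planted ground truth makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
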