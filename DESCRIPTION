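Package: scplate
Title: Plate-Based Barcoded-Bead Single-Cell RNA-seq Simulation and Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for microwell plate-based single-cell
    RNA-seq libraries built on barcoded capture beads: a paired-end read
    simulator with known ground truth (two-species barnyard plates,
    negative-control wells, ambient RNA, doublets, PCR duplicates,
    sequencing errors, drug-condition expression shifts), cell-barcode
    demultiplexing with Hamming-distance correction, k-mer transcript
    assignment, UMI collapse into a digital gene expression matrix,
    barnyard species classification and QC filtering, and a
    drug-response analysis stack (CPM normalization, PCA, graph
    clustering, Wilcoxon rank-sum differential expression with BH FDR,
    cell-cycle phase scoring, batch-effect removal, pseudobulk
    profiles).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    Biostrings,
    igraph,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
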