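Package: riboutr
Title: Translatome Analysis of UTR and Noncoding ORFs from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for staged translatome analysis from ribosome
    profiling (Ribo-seq) and RNA-seq: footprint quality control and P-site
    offset calibration, gene-level FPKM/RPKM quantification and translation
    efficiency (TE), discovery and classification of AUG-initiated ORFs in
    5' UTRs, 3' UTRs and noncoding transcripts via a 3-nucleotide
    periodicity test with Kozak-context scoring, TE-based gene
    classification, the translatome-versus-transcriptome expression
    variation statistic, max-normalized k-means coexpression clustering
    with hypergeometric enrichment, and corroboration of ORF calls by
    peptide and isoform evidence. Ships a synthetic-data generator that
    emulates a staged anther-development study design (ten stages, two
    replicates, 25-33 nt footprints, frame-biased P-sites, planted
    UTR-ORFs) with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    methods,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
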