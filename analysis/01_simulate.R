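#!/usr/bin/env Rscript
# Generate the synthetic staged-anther study: ten stages x two replicates,
# 500 coding genes + 80 intergenic noncoding transcripts, 420 planted
# UTR/noncoding ORFs (half translated), Ribo-seq P-site tracks with
# 3-nt frame bias and RNA-seq fragment counts. Everything downstream
# reads the plain-text outputs written here.

suppressPackageStartupMessages(library(riboutr))

cfg <- sim_config(seed = 1L)
sim <- simulate_dataset(cfg)
write_simulation(sim, "results/simdata")

orfs <- sim$truth$orfs
cat("genes:", cfg$n_genes,
    "| noncoding transcripts:", cfg$n_nc_transcripts, "\n")
cat("planted ORFs:", nrow(orfs), "(",
    sum(orfs$category == "five_prime_ORF"), "5' /",
    sum(orfs$category == "three_prime_ORF"), "3' /",
    sum(orfs$category == "ncORF"), "nc ) —",
    sum(orfs$translated), "translated,",
    sum(!orfs$translated), "untranslated\n")
cat("Ribo-seq P-sites:", sum(sim$ribo$track$count),
    "| RNA fragments:", sum(sim$rna$counts$count), "\n")
cat("wrote results/simdata/\n")
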