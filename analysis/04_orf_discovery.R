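#!/usr/bin/env Rscript
# Enumerate AUG..stop ORFs on every transcript, collapse same-stop
# candidates to the longest, classify by AUG location (5' UTR / 3' UTR /
# noncoding), test 3-nt periodicity on non-mORF-overlapping codons, and
# score Kozak context. Compared against the planted truth.

suppressPackageStartupMessages({library(riboutr); library(data.table)})

annot <- read_gff3("results/simdata/annotation.gff3")
genome <- read_genome("results/simdata/genome.fa")
track <- read_psites("results/simdata/psites.tsv")
stages <- fread("results/simdata/stages.tsv")
truth <- fread("results/simdata/truth_orfs.tsv")

orfs <- discover_orfs(annot, genome)
acc <- accept_translated(orfs, track, annot, stages$stage)
fwrite(acc$orfs, "results/orfs.tsv", sep = "\t")
fwrite(acc$orf_rpkm, "results/orf_rpkm.tsv", sep = "\t")
accepted <- acc$orfs[accepted == TRUE]
write_orfs_bed12(annot, accepted, "results/orfs.bed12")

cat("candidates:", nrow(orfs), "| accepted:", nrow(accepted), "(",
    sum(accepted$category == "five_prime_ORF"), "5' /",
    sum(accepted$category == "three_prime_ORF"), "3' /",
    sum(accepted$category == "ncORF"), "nc )\n")
cat(sprintf("strong Kozak among accepted: %.1f%%\n",
            100 * mean(accepted$kozak_strong)))

m <- merge(acc$orfs,
           truth[, .(tx_id, stop_tpos, translated, true_cat = category)],
           by = c("tx_id", "stop_tpos"), all.x = TRUE)
sens <- m[translated == TRUE, mean(accepted)]
fdp <- m[accepted == TRUE, mean(!(translated %in% TRUE))]
catok <- m[accepted == TRUE & translated %in% TRUE,
           mean(category == true_cat)]
cat(sprintf("vs truth: sensitivity %.3f, FDP %.3f, category accuracy %.3f\n",
            sens, fdp, catok))
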