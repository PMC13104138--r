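#!/usr/bin/env Rscript
# Footprint QC: length distribution and per-frame P-site fractions over
# annotated CDS, the two standard diagnostics that the libraries behave
# like ribosome footprints.

suppressPackageStartupMessages({library(riboutr); library(data.table)})

annot <- read_gff3("results/simdata/annotation.gff3")
track <- read_psites("results/simdata/psites.tsv",
                     chromosomes = annot$chromosomes)

lh <- length_histogram(track)
fwrite(lh$hist, "results/length_hist.tsv", sep = "\t")
cat(sprintf("footprints in 25-33 nt: %.1f%% | in 25-30 nt: %.1f%%\n",
            100 * lh$fraction_25_33, 100 * lh$fraction_25_30))

# frame fractions over mORF codons, per stage (replicates pooled)
map <- tx_map(annot)
cds <- annot$transcripts[!is.na(cds_tstart),
                         .(tx_id, cds_tstart, cds_tend)]
tt <- track[map, on = .(chrom, strand, pos = gpos), nomatch = NULL]
tt <- tt[cds, on = "tx_id", nomatch = NULL][
  tpos >= cds_tstart & tpos < cds_tend]
tt[, stage := tstrsplit(sample, "_r", fixed = TRUE)[[1]]]
tt[, frame := (tpos - cds_tstart) %% 3L]
ff <- dcast(tt[, .(n = sum(count)), by = .(stage, frame)],
            stage ~ frame, value.var = "n")
setnames(ff, c("0", "1", "2"), c("n0", "n1", "n2"))
ff[, f0 := n0 / (n0 + n1 + n2)]
fwrite(ff, "results/frame_fractions.tsv", sep = "\t")
cat(sprintf("frame-0 fraction over mORFs: %.3f-%.3f across stages\n",
            min(ff$f0), max(ff$f0)))
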