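#!/usr/bin/env Rscript
# TE-based gene classes (high / very-high / low / fluctuating), the
# translatome-vs-transcriptome expression-variation statistic, and
# ORF-feature-vs-TE relationships.

suppressPackageStartupMessages({library(riboutr); library(data.table)})

read_mat <- function(f) {
  dt <- fread(f)
  m <- as.matrix(dt[, -1]); rownames(m) <- dt$gene_id
  m
}
fpkm <- read_mat("results/fpkm.tsv")
rpkm <- read_mat("results/rpkm.tsv")
stages <- fread("results/simdata/stages.tsv")
expr <- structure(list(rna = fpkm, ribo = rpkm, stages = stages$stage),
                  class = "ExpressionMatrix")
te <- compute_te(expr)
pm <- setNames(stages$phase, stages$stage)

cl <- classify_te(expr, te, phase_map = pm)
fwrite(cl$genes, "results/te_classes.tsv", sep = "\t")
cat("TE classes:\n"); print(table(cl$genes$class))

ev <- expression_variation(fpkm, rpkm, min_median = 1)
fwrite(ev$report, "results/variance_report.tsv", sep = "\t")
cat(sprintf("expression variation increase (log2 scale): %.1f%% to %.1f%% across stages (%d genes)\n",
            min(ev$report$pct_increase_log2),
            max(ev$report$pct_increase_log2), ev$filter$n_used))

orfs <- fread("results/orfs.tsv")[accepted == TRUE]
orf_rpkm <- fread("results/orf_rpkm.tsv")
rel <- orf_te_relations(orfs, orf_rpkm, te)
fwrite(rel$per_orf, "results/orf_te_relations.tsv", sep = "\t")
fwrite(rel$length_correlation, "results/orf_length_te_corr.tsv",
       sep = "\t")
cat("ORF length vs host TE (Spearman):\n")
print(rel$length_correlation)
for (cls in names(rel$kozak_groups)) {
  cat("TE by Kozak groups for", cls, "(Tukey letters):\n")
  print(rel$kozak_groups[[cls]]$groups)
}
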