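#!/usr/bin/env Rscript
# Cross-evidence for accepted ORFs: peptide-to-ORF substring matches
# (with reversed decoys) and containment of ORFs in independent isoform
# models.

suppressPackageStartupMessages({library(riboutr); library(data.table)})

annot <- read_gff3("results/simdata/annotation.gff3")
orfs <- fread("results/orfs.tsv")[accepted == TRUE]
peptides <- fread("results/simdata/peptides.tsv")

mp <- match_peptides(peptides, setNames(orfs$peptide, orfs$orf_id))
fwrite(mp$matches, "results/peptide_matches.tsv", sep = "\t")
dec <- peptides[decoy == TRUE, peptide]
cat(sprintf("peptides matched to accepted ORFs: %d of %d true, decoy hits: %d of %d\n",
            length(unique(mp$matches$peptide[!(mp$matches$peptide %in% dec)])),
            peptides[decoy == FALSE, .N],
            sum(dec %in% mp$matches$peptide), length(dec)))

if (file.exists("results/simdata/isoforms.gff3")) {
  isoforms <- read_gff3("results/simdata/isoforms.gff3")
  iso <- isoform_support(orfs, annot, isoforms)
  fwrite(iso, "results/isoform_support.tsv", sep = "\t")
  truth <- fread("results/simdata/truth_orfs.tsv")
  m <- merge(orfs, truth[, .(tx_id, stop_tpos, isoform_backed)],
             by = c("tx_id", "stop_tpos"), all.x = TRUE)
  backed <- m[isoform_backed %in% TRUE, orf_id]
  supp <- unique(iso[supported == TRUE, orf_id])
  cat(sprintf("isoform-backed accepted ORFs supported: %d / %d; non-backed flagged: %d\n",
              sum(backed %in% supp), length(backed),
              sum(!(supp %in% backed))))
}
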