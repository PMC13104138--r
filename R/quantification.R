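#' Count P-sites / fragments over gene features
#'
#' Gene-level counting against the union of each gene's exon (RNA) or CDS
#' (Ribo) intervals, strand-matched. A placement overlapping features of
#' several genes contributes one count to each (multi-overlap counting,
#' mirroring featureCounts' `-O` behaviour).
#'
#' @param track placement/P-site track ([psite_track()]).
#' @param annot an [annotation_set()].
#' @param feature `"CDS"` or `"exon"`.
#' @return data.table `sample`, `gene_id`, `count` (genes without hits
#'   absent; join against the gene universe to zero-fill).
#' @export
count_features <- function(track, annot, feature = c("CDS", "exon")) {
  feature <- match.arg(feature)
  unknown <- setdiff(unique(track$chrom), names(annot$chromosomes))
  assert_that(length(unknown) == 0L,
              paste("placements on unknown chromosome(s):",
                    paste(unknown, collapse = ", ")))
  feats <- if (feature == "exon") {
    annot$exons[, .(tx_id, chrom, strand, start, end)]
  } else {
    annot$transcripts[, .(tx_id, chrom, strand)][annot$cds, on = "tx_id"]
  }
  feats <- annot$transcripts[, .(tx_id, gene_id)][feats, on = "tx_id"]
  if (nrow(feats) == 0L || nrow(track) == 0L) {
    return(data.table::data.table(sample = character(),
                                  gene_id = character(), count = integer()))
  }
  # union of intervals per gene
  gr <- GenomicRanges::GRanges(feats$chrom,
                               IRanges::IRanges(feats$start + 1L,
                                                feats$end),
                               strand = feats$strand)
  red <- GenomicRanges::reduce(GenomicRanges::split(gr, feats$gene_id))
  red_flat <- unlist(red)
  pos <- GenomicRanges::GRanges(track$chrom,
                                IRanges::IRanges(track$pos + 1L, width = 1L),
                                strand = track$strand)
  hits <- GenomicRanges::findOverlaps(pos, red_flat)
  if (length(hits) == 0L) {
    return(data.table::data.table(sample = character(),
                                  gene_id = character(), count = integer()))
  }
  dt <- data.table::data.table(
    sample = track$sample[S4Vectors::queryHits(hits)],
    gene_id = names(red_flat)[S4Vectors::subjectHits(hits)],
    count = track$count[S4Vectors::queryHits(hits)])
  dt[, .(count = sum(count)), by = .(sample, gene_id)]
}

#' Union feature lengths per gene
#'
#' @param annot an [annotation_set()].
#' @param feature `"CDS"` or `"exon"`.
#' @return data.table `gene_id`, `length_bp`, `length_kb` (length of the
#'   union of the gene's feature intervals).
#' @export
gene_feature_lengths <- function(annot, feature = c("CDS", "exon")) {
  feature <- match.arg(feature)
  feats <- if (feature == "exon") {
    annot$exons[, .(tx_id, chrom, start, end)]
  } else {
    tmp <- annot$transcripts[, .(tx_id, chrom)][annot$cds, on = "tx_id"]
    tmp[, .(tx_id, chrom, start, end)]
  }
  feats <- annot$transcripts[, .(tx_id, gene_id)][feats, on = "tx_id"]
  if (nrow(feats) == 0L) {
    return(data.table::data.table(gene_id = character(),
                                  length_bp = integer(),
                                  length_kb = numeric()))
  }
  gr <- GenomicRanges::GRanges(feats$chrom,
                               IRanges::IRanges(feats$start + 1L, feats$end))
  red <- GenomicRanges::reduce(GenomicRanges::split(gr, feats$gene_id))
  len <- sum(GenomicRanges::width(red))
  data.table::data.table(gene_id = names(len),
                         length_bp = as.integer(len),
                         length_kb = as.numeric(len) / 1000)
}

#' FPKM / RPKM normalization
#'
#' `value = count / length_kb / total_mapped_millions`. Linear in counts
#' and inverse-linear in feature length; doubling all counts and the
#' library total leaves values unchanged.
#'
#' @param counts numeric vector of raw counts.
#' @param length_kb feature lengths in kilobases (recycled).
#' @param total_millions total mapped reads/fragments of the library, in
#'   millions (recycled).
#' @return numeric vector of FPKM/RPKM values.
#' @export
normalize_fpkm <- function(counts, length_kb, total_millions) {
  bad <- which(length_kb <= 0)
  assert_that(length(bad) == 0L,
              paste("zero/negative feature length at position(s):",
                    paste(utils::head(bad, 5L), collapse = ", ")))
  assert_that(all(total_millions > 0), "library total must be > 0")
  counts / length_kb / total_millions
}

#' Assemble the gene x stage expression matrix
#'
#' Normalizes each replicate library to FPKM (RNA over union exon length)
#' or RPKM (Ribo over union CDS length), using the sum of counted
#' placements per library as the mapped total, then averages replicates
#' per stage. Only genes with a CDS (coding genes) populate the Ribo
#' layer.
#'
#' @param annot an [annotation_set()].
#' @param rna_counts data.table `gene_id`, `stage`, `rep`, `count`.
#' @param ribo_track a P-site track whose `sample` is `"<stage>_r<rep>"`,
#'   or a pre-counted data.table `gene_id`, `stage`, `rep`, `count`.
#' @param stages character vector giving stage order.
#' @return an `ExpressionMatrix`: list with matrices `rna` and `ribo`
#'   (genes x stages, replicate means), replicate-level tables
#'   `rna_reps` / `ribo_reps`, `exon_kb` / `cds_kb`, `lib_sizes`, and
#'   `stages`.
#' @export
quantify_expression <- function(annot, rna_counts, ribo_track, stages) {
  rna_counts <- data.table::as.data.table(rna_counts)
  if (!is.null(ribo_track) && "pos" %in% names(ribo_track)) {
    rc <- count_features(ribo_track, annot, "CDS")
    rc[, c("stage", "rep") := data.table::tstrsplit(sample, "_r",
                                                    fixed = TRUE)]
    rc[, rep := as.integer(rep)]
    ribo_counts <- rc[, .(gene_id, stage, rep, count)]
  } else {
    ribo_counts <- data.table::as.data.table(ribo_track)
  }
  exon_len <- gene_feature_lengths(annot, "exon")
  cds_len <- gene_feature_lengths(annot, "CDS")
  coding_genes <- sort(unique(
    annot$transcripts[biotype == "protein_coding", gene_id]))

  layer <- function(counts, len, genes) {
    full <- data.table::CJ(gene_id = genes,
                           stage = stages,
                           rep = sort(unique(counts$rep)))
    full <- merge(full, counts, by = c("gene_id", "stage", "rep"),
                  all.x = TRUE)
    full[is.na(count), count := 0L]
    libs <- full[, .(total = sum(count)), by = .(stage, rep)]
    full <- merge(full, libs, by = c("stage", "rep"))
    full <- merge(full, len[, .(gene_id, length_kb)], by = "gene_id")
    full[, value := normalize_fpkm(count, length_kb, total / 1e6)]
    means <- full[, .(value = mean(value)), by = .(gene_id, stage)]
    m <- data.table::dcast(means, gene_id ~ stage, value.var = "value")
    mat <- as.matrix(m[, -1]); rownames(mat) <- m$gene_id
    list(mat = mat[, stages, drop = FALSE], reps = full, libs = libs)
  }
  rna <- layer(rna_counts, exon_len,
               sort(unique(annot$genes$gene_id)))
  ribo <- layer(ribo_counts, cds_len, coding_genes)
  structure(list(rna = rna$mat, ribo = ribo$mat,
                 rna_reps = rna$reps, ribo_reps = ribo$reps,
                 exon_kb = stats::setNames(exon_len$length_kb,
                                           exon_len$gene_id),
                 cds_kb = stats::setNames(cds_len$length_kb,
                                          cds_len$gene_id),
                 lib_sizes = list(rna = rna$libs, ribo = ribo$libs),
                 stages = stages),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$rna), "genes (RNA),", nrow(x$ribo),
      "genes (Ribo),", length(x$stages), "stages\n")
  invisible(x)
}

#' Translation efficiency profile
#'
#' `TE = (RPKM + 1) / (FPKM + 1)`, elementwise on replicate-mean values,
#' with pseudocount 1 on both layers. TE is 1 exactly when both layers
#' are 0, and always positive.
#'
#' @param expr an `ExpressionMatrix` ([quantify_expression()]).
#' @param pseudocount pseudocount constant (1).
#' @return a `TEProfile`: list with `te` (genes x stages matrix over
#'   genes present in both layers) and `pseudocount`.
#' @export
compute_te <- function(expr, pseudocount = 1) {
  genes <- intersect(rownames(expr$rna), rownames(expr$ribo))
  te <- (expr$ribo[genes, , drop = FALSE] + pseudocount) /
    (expr$rna[genes, , drop = FALSE] + pseudocount)
  structure(list(te = te, pseudocount = pseudocount), class = "TEProfile")
}

#' Expressed / translated gene calling
#'
#' A gene is transcribed at a stage iff its replicate-mean FPKM is at
#' least `threshold` (inclusive), translated iff RPKM is at least
#' `threshold`.
#'
#' @param expr an `ExpressionMatrix`.
#' @param threshold inclusive FPKM/RPKM cutoff (default 1).
#' @return list with logical matrices `transcribed` and `translated`
#'   (genes x stages) and a per-stage `summary` data.table with set sizes
#'   and the fraction of transcribed genes translated (and vice versa),
#'   computed over coding genes present in both layers.
#' @export
call_expressed <- function(expr, threshold = 1) {
  transcribed <- expr$rna >= threshold
  translated <- expr$ribo >= threshold
  genes <- intersect(rownames(transcribed), rownames(translated))
  tsub <- transcribed[genes, , drop = FALSE]
  rsub <- translated[genes, , drop = FALSE]
  summary <- data.table::rbindlist(lapply(expr$stages, function(s) {
    nt <- sum(tsub[, s]); nr <- sum(rsub[, s])
    nb <- sum(tsub[, s] & rsub[, s])
    data.table::data.table(
      stage = s, n_transcribed = nt, n_translated = nr, n_both = nb,
      frac_transcribed_translated = if (nt > 0) nb / nt else NA_real_,
      frac_translated_transcribed = if (nr > 0) nb / nr else NA_real_)
  }))
  list(transcribed = transcribed, translated = translated,
       summary = summary)
}
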