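#' Gene-model container used throughout the pipeline
#'
#' An `AnnotationSet` holds chromosome lengths, genes, transcripts with
#' ordered exons, and CDS intervals. All internal coordinates are 0-based
#' half-open; on-disk formats keep their native conventions (GFF3 1-based
#' inclusive, BED 0-based half-open). Exons are ranked 5' to 3' in
#' transcript orientation, so rank 1 always contains the transcript's 5'
#' end. 5' and 3' UTRs are inferred, not stored: in transcript coordinates
#' the 5' UTR is `[0, cds_tstart)` and the 3' UTR is `[cds_tend, tx_len)`.
#'
#' @param chromosomes named integer vector of chromosome lengths (bp).
#' @param genes data.table with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open).
#' @param transcripts data.table with `tx_id`, `gene_id`, `biotype`
#'   (`"protein_coding"` or `"noncoding"`).
#' @param exons data.table with `tx_id`, `start`, `end` (genome, 0-based
#'   half-open; strand taken from the parent gene).
#' @param cds data.table with `tx_id`, `start`, `end`; may be empty.
#' @param provenance optional list recording source file and checksum.
#'
#' @return An object of class `AnnotationSet`: a list with elements
#'   `chromosomes`, `genes`, `transcripts` (gaining `chrom`, `strand`,
#'   `tx_len`, `cds_tstart`, `cds_tend`, `cds_len`, `cds_len_ok`), `exons`
#'   (gaining `chrom`, `strand`, `exon_rank`, `toffset`), `cds`, and
#'   `provenance`. Transcripts whose CDS length is not a multiple of 3 are
#'   flagged via `cds_len_ok = FALSE`, never silently accepted.
#' @export
annotation_set <- function(chromosomes, genes, transcripts, exons, cds = NULL,
                           provenance = list()) {
  genes <- data.table::as.data.table(genes)
  transcripts <- data.table::as.data.table(transcripts)
  exons <- data.table::as.data.table(exons)
  cds <- if (is.null(cds) || nrow(cds) == 0L) {
    data.table::data.table(tx_id = character(), start = integer(),
                           end = integer())
  } else data.table::as.data.table(cds)

  assert_that(!is.null(names(chromosomes)), "chromosomes must be named")
  assert_that(all(genes$chrom %in% names(chromosomes)),
              "gene on unknown chromosome")
  assert_that(all(genes$strand %in% c("+", "-")), "gene strand must be +/-")
  assert_that(all(transcripts$gene_id %in% genes$gene_id),
              "transcript with unknown parent gene")
  assert_that(all(exons$tx_id %in% transcripts$tx_id),
              "exon with unknown parent transcript")
  assert_that(all(cds$tx_id %in% transcripts$tx_id),
              "CDS with unknown parent transcript")

  gkey <- genes[, .(gene_id, chrom, strand)]
  transcripts <- gkey[transcripts, on = "gene_id"]
  exons <- transcripts[, .(tx_id, chrom, strand)][exons, on = "tx_id"]
  assert_that(all(exons$end > exons$start), "empty exon interval")
  assert_that(all(exons$start >= 0L), "negative exon coordinate")
  ex_chk <- merge(exons, data.table::data.table(
    chrom = names(chromosomes), chrom_len = as.integer(chromosomes)),
    by = "chrom")
  assert_that(all(ex_chk$end <= ex_chk$chrom_len),
              "exon exceeds chromosome length")

  # rank exons 5'->3' in transcript orientation, cumulative toffset
  exons[, exon_rank := {
    o <- if (strand[1] == "+") order(start) else order(-start)
    r <- integer(.N); r[o] <- seq_len(.N); r
  }, by = tx_id]
  data.table::setorder(exons, tx_id, exon_rank)
  exons[, width := end - start]
  exons[, toffset := cumsum(data.table::shift(width, fill = 0L)), by = tx_id]
  # exons within a transcript must be disjoint
  chk <- exons[order(tx_id, start),
               .(ok = all(start[-1] >= end[-.N]) || .N == 1L), by = tx_id]
  assert_that(all(chk$ok), "overlapping exons within a transcript")

  tlen <- exons[, .(tx_len = sum(width)), by = tx_id]
  transcripts <- tlen[transcripts, on = "tx_id"]

  # map CDS intervals to transcript coordinates, validating containment
  transcripts[, `:=`(cds_tstart = NA_integer_, cds_tend = NA_integer_,
                     cds_len = 0L, cds_len_ok = NA)]
  if (nrow(cds) > 0L) {
    cm <- exons[cds, on = .(tx_id, start <= start, end >= end),
                .(tx_id, cstart = i.start, cend = i.end,
                  estart = x.start, eend = x.end, toffset, strand)]
    if (anyNA(cm$toffset)) {
      bad <- cm[is.na(toffset), tx_id]
      stop("CDS interval outside exons for transcript(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    cm[, `:=`(
      tlo = ifelse(strand == "+", toffset + (cstart - estart),
                   toffset + (eend - cend)),
      w = cend - cstart
    )]
    csum <- cm[, .(cds_tstart = min(tlo), cds_tend = max(tlo + w),
                   cds_len = sum(w)), by = tx_id]
    bad <- csum[cds_tend - cds_tstart != cds_len, tx_id]
    assert_that(length(bad) == 0L,
                paste("CDS not contiguous in transcript space:",
                      paste(bad, collapse = ", ")))
    transcripts[csum, on = "tx_id", `:=`(
      cds_tstart = i.cds_tstart, cds_tend = i.cds_tend, cds_len = i.cds_len,
      cds_len_ok = i.cds_len %% 3L == 0L)]
  }
  coding_with_cds <- transcripts[biotype == "protein_coding" & cds_len == 0L]
  assert_that(nrow(coding_with_cds) == 0L,
              "protein_coding transcript without CDS")

  structure(list(chromosomes = chromosomes,
                 genes = genes,
                 transcripts = transcripts[, .(
                   tx_id, gene_id, chrom, strand, biotype, tx_len,
                   cds_tstart, cds_tend, cds_len, cds_len_ok)],
                 exons = exons[, .(tx_id, chrom, strand, start, end,
                                   exon_rank, width, toffset)],
                 cds = cds,
                 provenance = provenance),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", length(x$chromosomes), "chromosome(s),",
      nrow(x$genes), "gene(s),", nrow(x$transcripts), "transcript(s)\n")
  invisible(x)
}

#' Position map between transcript and genome coordinates
#'
#' Expands the exon structure of the requested transcripts into a lookup
#' table with one row per transcript position, ordered 5' to 3'.
#'
#' @param annot an [annotation_set()].
#' @param tx_ids transcripts to expand (default: all).
#' @return data.table with columns `tx_id`, `chrom`, `strand`, `tpos`
#'   (0-based position in the spliced transcript) and `gpos` (0-based
#'   genome position).
#' @export
tx_map <- function(annot, tx_ids = NULL) {
  ex <- annot$exons
  if (!is.null(tx_ids)) ex <- ex[tx_id %in% tx_ids]
  if (nrow(ex) == 0L) {
    return(data.table::data.table(tx_id = character(), chrom = character(),
                                  strand = character(), tpos = integer(),
                                  gpos = integer()))
  }
  idx <- rep(seq_len(nrow(ex)), ex$width)
  off <- sequence(ex$width) - 1L
  plus <- ex$strand[idx] == "+"
  data.table::data.table(
    tx_id = ex$tx_id[idx],
    chrom = ex$chrom[idx],
    strand = ex$strand[idx],
    tpos = ex$toffset[idx] + off,
    gpos = ifelse(plus, ex$start[idx] + off, ex$end[idx] - 1L - off)
  )
}

#' Spliced transcript sequence with position maps
#'
#' @param annot an [annotation_set()].
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param transcript_id a single transcript id.
#' @return A `TranscriptSequence`: list with `tx_id`, `seq` (spliced
#'   sequence in transcript orientation, reverse-complemented on the minus
#'   strand), `gpos` (genome position of each transcript position), `chrom`
#'   and `strand`. Round-trip mapping transcript -> genome -> transcript is
#'   the identity.
#' @export
spliced_sequence <- function(annot, genome, transcript_id) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome),
                              sub("\\s.*$", "", names(genome)))
  }
  ex <- annot$exons[tx_id == transcript_id][order(exon_rank)]
  assert_that(nrow(ex) > 0L, paste("unknown transcript:", transcript_id))
  chrom <- ex$chrom[1]
  assert_that(chrom %in% names(genome),
              paste("chromosome missing from genome:", chrom))
  chrom_seq <- genome[[chrom]]
  assert_that(max(ex$end) <= nchar(chrom_seq),
              "exon exceeds chromosome length in FASTA")
  pieces <- substring(chrom_seq, ex$start + 1L, ex$end)
  if (ex$strand[1] == "-") pieces <- revcomp(pieces)
  map <- tx_map(annot, transcript_id)
  structure(list(tx_id = transcript_id,
                 seq = paste(pieces, collapse = ""),
                 gpos = map$gpos, chrom = chrom, strand = ex$strand[1]),
            class = "TranscriptSequence")
}

gff3_tx_types <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "lncRNA",
                   "antisense_RNA", "snoRNA", "snRNA", "miRNA", "tRNA",
                   "rRNA")

#' Read a GFF3 gene annotation
#'
#' Parses gene / transcript / exon / CDS features (via
#' [rtracklayer::import()]) into an [annotation_set()]. GFF3 coordinates
#' are 1-based inclusive on disk and converted to the internal 0-based
#' half-open convention. UTRs are inferred from exon/CDS structure;
#' explicit UTR features are ignored. Transcripts without CDS children are
#' treated as noncoding.
#'
#' @param path path to a GFF3 file.
#' @param chromosomes optional named integer vector of chromosome lengths;
#'   when absent, lengths come from `##sequence-region` pragmas or, failing
#'   that, the maximum annotated end per chromosome.
#' @return an [annotation_set()].
#' @export
read_gff3 <- function(path, chromosomes = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    ID = as.character(gr$ID %||% NA_character_),
    Parent = vapply(as.list(gr$Parent %||% character(nrow = 0)),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  )
  genes <- dt[type == "gene", .(gene_id = ID, chrom, strand, start, end)]
  assert_that(!anyNA(genes$gene_id), "gene feature without ID")
  txs <- dt[type %in% gff3_tx_types]
  bad <- txs[!(Parent %in% genes$gene_id)]
  if (nrow(bad) > 0L) {
    stop("transcript feature(s) with malformed gene link: ",
         paste(bad$ID, collapse = ", "), call. = FALSE)
  }
  ex <- dt[type == "exon"]
  bad <- ex[!(Parent %in% txs$ID)]
  if (nrow(bad) > 0L) {
    stop("exon feature(s) with malformed transcript link: ",
         paste(ifelse(is.na(bad$ID), "<no ID>", bad$ID), collapse = ", "),
         call. = FALSE)
  }
  cd <- dt[type == "CDS"]
  bad <- cd[!(Parent %in% txs$ID)]
  if (nrow(bad) > 0L) {
    stop("CDS feature(s) with malformed transcript link: ",
         paste(ifelse(is.na(bad$ID), "<no ID>", bad$ID), collapse = ", "),
         call. = FALSE)
  }
  coding <- unique(cd$Parent)
  transcripts <- txs[, .(tx_id = ID, gene_id = Parent,
                         biotype = ifelse(ID %in% coding, "protein_coding",
                                          "noncoding"))]
  if (is.null(chromosomes)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (length(sl) > 0L && all(!is.na(sl))) {
      chromosomes <- stats::setNames(as.integer(sl), names(sl))
    } else {
      # fall back to ##sequence-region pragmas, then to max feature end
      hdr <- grep("^##sequence-region", readLines(path, n = 10000L),
                  value = TRUE)
      if (length(hdr) > 0L) {
        parts <- strsplit(trimws(hdr), "\\s+")
        chromosomes <- stats::setNames(
          vapply(parts, function(x) as.integer(x[4]), integer(1)),
          vapply(parts, function(x) x[2], character(1)))
      } else {
        mx <- dt[, .(len = max(end)), by = chrom]
        chromosomes <- stats::setNames(mx$len, mx$chrom)
      }
    }
  }
  annotation_set(chromosomes = chromosomes, genes = genes,
                 transcripts = transcripts,
                 exons = ex[, .(tx_id = Parent, start, end)],
                 cds = cd[, .(tx_id = Parent, start, end)],
                 provenance = list(source = path,
                                   md5 = unname(tools::md5sum(path))))
}

#' Write an AnnotationSet as GFF3
#'
#' Emits gene, mRNA/ncRNA, exon and CDS features with 1-based inclusive
#' coordinates and `##sequence-region` pragmas, such that
#' `read_gff3(write_gff3(x))` reproduces all feature coordinates exactly.
#'
#' @param annot an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annot, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(annot$chromosomes),
                     as.integer(annot$chromosomes)))
  g <- annot$genes[order(chrom, start)]
  tx <- annot$transcripts
  fmt <- function(chrom, type, start, end, strand, attrs, phase = ".") {
    sprintf("%s\triboutr\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, start + 1L, end, strand, phase, attrs)
  }
  lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand,
                        sprintf("ID=%s", g$gene_id)))
  tx2 <- merge(tx,
               annot$exons[, .(start = min(start), end = max(end)),
                           by = tx_id], by = "tx_id")
  lines <- c(lines, fmt(tx2$chrom,
                        ifelse(tx2$biotype == "protein_coding", "mRNA",
                               "ncRNA"),
                        tx2$start, tx2$end, tx2$strand,
                        sprintf("ID=%s;Parent=%s", tx2$tx_id, tx2$gene_id)))
  ex <- annot$exons
  lines <- c(lines, fmt(ex$chrom, "exon", ex$start, ex$end, ex$strand,
                        sprintf("ID=%s:exon%d;Parent=%s", ex$tx_id,
                                ex$exon_rank, ex$tx_id)))
  if (nrow(annot$cds) > 0L) {
    cd <- merge(annot$cds, tx[, .(tx_id, chrom, strand)], by = "tx_id")
    # phase per CDS piece in translation order
    data.table::setorder(cd, tx_id, start)
    cd[, ord := if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N)),
       by = tx_id]
    data.table::setorder(cd, tx_id, ord)
    cd[, phase := {
      before <- cumsum(data.table::shift(end - start, fill = 0L))
      as.integer((3L - before %% 3L) %% 3L)
    }, by = tx_id]
    lines <- c(lines, fmt(cd$chrom, "CDS", cd$start, cd$end, cd$strand,
                          sprintf("ID=%s:cds;Parent=%s", cd$tx_id, cd$tx_id),
                          phase = as.character(cd$phase)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences (names truncated
#'   at the first whitespace).
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write genome sequences to FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}

psite_cols <- c("sample", "chrom", "strand", "pos", "read_length", "count")

empty_psite_track <- function() {
  data.table::data.table(sample = character(), chrom = character(),
                         strand = character(), pos = integer(),
                         read_length = integer(), count = integer())
}

#' Validate and aggregate a P-site track
#'
#' A P-site track is a data.table with columns `sample`, `chrom`, `strand`
#' (`"+"`/`"-"`), `pos` (0-based genome position of the ribosomal P-site),
#' `read_length` (footprint length in nt, `NA` when unrecorded) and
#' `count`. Rows sharing all keys are summed.
#'
#' @param dt data.frame/data.table with the columns above (`read_length`
#'   optional).
#' @param chromosomes optional named lengths; positions at or beyond the
#'   chromosome length are a hard error.
#' @return aggregated data.table in canonical column order.
#' @export
psite_track <- function(dt, chromosomes = NULL) {
  dt <- data.table::as.data.table(dt)
  if (nrow(dt) == 0L) return(empty_psite_track())
  if (!"read_length" %in% names(dt)) dt[, read_length := NA_integer_]
  missing <- setdiff(psite_cols, names(dt))
  assert_that(length(missing) == 0L,
              paste("P-site track missing column(s):",
                    paste(missing, collapse = ", ")))
  assert_that(all(dt$count >= 0), "negative P-site count")
  assert_that(all(dt$pos >= 0), "negative P-site position")
  assert_that(all(dt$strand %in% c("+", "-")), "strand must be +/-")
  if (!is.null(chromosomes)) {
    chk <- merge(dt[, .(chrom, pos)],
                 data.table::data.table(chrom = names(chromosomes),
                                        len = as.integer(chromosomes)),
                 by = "chrom", all.x = TRUE)
    assert_that(!anyNA(chk$len), "P-site on unknown chromosome")
    assert_that(all(chk$pos < chk$len),
                "P-site position beyond chromosome length")
  }
  out <- dt[, .(count = as.integer(sum(count))),
            by = .(sample, chrom, strand, pos, read_length)]
  data.table::setcolorder(out, psite_cols)
  out[]
}

#' Read a P-site (or 5'-end placement) track from TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `pos`,
#' `strand`, `count`, `sample` and optionally `read_length`. An empty file
#' yields an empty track, not an error.
#'
#' @inheritParams psite_track
#' @param path TSV path.
#' @return aggregated P-site track (see [psite_track()]).
#' @export
read_psites <- function(path, chromosomes = NULL) {
  if (file.size(path) == 0L) return(empty_psite_track())
  dt <- data.table::fread(path, sep = "\t")
  if (nrow(dt) == 0L) return(empty_psite_track())
  psite_track(dt, chromosomes = chromosomes)
}

#' Write a P-site track to TSV
#' @param track a P-site track ([psite_track()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psites <- function(track, path) {
  data.table::fwrite(track, path, sep = "\t")
  invisible(path)
}
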