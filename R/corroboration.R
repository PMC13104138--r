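#' Match MS peptides to ORF protein sequences
#'
#' Exact substring search of each peptide against every ORF peptide
#' (optionally collapsing I and L, which are isobaric in MS). All
#' matching ORFs are reported per peptide; peptides shorter than
#' `min_len` are skipped and recorded.
#'
#' @param peptides character vector of uppercase amino-acid strings, or
#'   a data.table with a `peptide` column (extra columns such as `decoy`
#'   are carried through).
#' @param orf_peptides named character vector: ORF id -> amino-acid
#'   sequence.
#' @param min_len minimum peptide length to search (default 7).
#' @param il_equivalent treat I and L as identical (default `FALSE`).
#' @return list with `matches` (data.table `peptide`, `orf_id`,
#'   `offset` 0-based within the ORF peptide, one row per occurrence)
#'   and `skipped` (peptides below `min_len`).
#' @export
match_peptides <- function(peptides, orf_peptides, min_len = 7L,
                           il_equivalent = FALSE) {
  pep_dt <- if (is.character(peptides)) {
    data.table::data.table(peptide = peptides)
  } else data.table::as.data.table(peptides)
  canon <- function(x) if (il_equivalent) chartr("I", "L", x) else x
  skipped <- pep_dt[nchar(peptide) < min_len]
  search <- pep_dt[nchar(peptide) >= min_len]
  targets <- canon(orf_peptides)
  res <- list()
  for (i in seq_len(nrow(search))) {
    pep <- search$peptide[i]
    q <- canon(pep)
    hit_ids <- names(targets)[vapply(targets, function(t)
      grepl(q, t, fixed = TRUE), logical(1))]
    for (oid in hit_ids) {
      offs <- as.integer(gregexpr(q, targets[[oid]], fixed = TRUE)[[1]]) - 1L
      res[[length(res) + 1L]] <- data.table::data.table(
        peptide = pep, orf_id = oid, offset = offs)
    }
  }
  matches <- if (length(res)) data.table::rbindlist(res) else
    data.table::data.table(peptide = character(), orf_id = character(),
                           offset = integer())
  list(matches = matches, skipped = skipped)
}

#' Structural support of ORFs by transcript isoforms
#'
#' An isoform supports an ORF iff (a) every genomic position of the ORF
#' lies within the isoform's exons, (b) strands match, and (c) the
#' isoform's splicing preserves the ORF sequence: consecutive ORF bases
#' remain adjacent in the isoform's spliced coordinates, keeping AUG and
#' stop intact in a single reading frame. Each ORF is compared against
#' every isoform transcript on its chromosome.
#'
#' @param orfs data.table with `orf_id`, `tx_id`, `t_start`, `t_end`
#'   (host transcript coordinates).
#' @param annot host [annotation_set()].
#' @param isoforms an [annotation_set()] of isoform models sharing the
#'   assembly.
#' @return data.table `orf_id`, `isoform_id`, `contained`,
#'   `strand_match`, `frame_intact`, `supported`; one row per
#'   (ORF, candidate isoform) with genomic overlap, plus a summary row
#'   possibility via `any(supported)` per ORF.
#' @export
isoform_support <- function(orfs, annot, isoforms) {
  unknown <- setdiff(names(isoforms$chromosomes),
                     names(annot$chromosomes))
  assert_that(length(unknown) == 0L,
              paste("isoform assembly mismatch; unknown chromosome(s):",
                    paste(unknown, collapse = ", ")))
  iso_map <- tx_map(isoforms)
  data.table::setnames(iso_map, c("tx_id", "tpos"),
                       c("isoform_id", "iso_tpos"))
  iso_tx <- isoforms$transcripts[, .(isoform_id = tx_id,
                                     iso_strand = strand)]
  res <- list()
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i]
    host <- annot$transcripts[tx_id == o$tx_id]
    m <- tx_map(annot, o$tx_id)[tpos >= o$t_start & tpos < o$t_end]
    data.table::setorder(m, tpos)  # 5'->3' along the ORF
    cand <- iso_map[chrom == host$chrom][gpos %in% m$gpos]
    if (nrow(cand) == 0L) next
    for (iso in unique(cand$isoform_id)) {
      im <- cand[isoform_id == iso]
      strand_match <- iso_tx[isoform_id == iso, iso_strand] == host$strand
      hit <- merge(m[, .(tpos, gpos)], im[, .(gpos, iso_tpos)],
                   by = "gpos", all.x = TRUE)
      data.table::setorder(hit, tpos)
      contained <- !anyNA(hit$iso_tpos)
      # both coordinate systems run 5'->3', so on matching strands the
      # isoform position must advance by exactly 1 per ORF base for the
      # spliced ORF sequence (AUG..stop, one frame) to survive intact
      frame_intact <- contained && strand_match &&
        all(diff(hit$iso_tpos) == 1L)
      res[[length(res) + 1L]] <- data.table::data.table(
        orf_id = o$orf_id, isoform_id = iso,
        contained = contained, strand_match = strand_match,
        frame_intact = frame_intact,
        supported = contained && strand_match && frame_intact)
    }
  }
  if (length(res) == 0L) {
    return(data.table::data.table(
      orf_id = character(), isoform_id = character(),
      contained = logical(), strand_match = logical(),
      frame_intact = logical(), supported = logical()))
  }
  data.table::rbindlist(res)
}
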