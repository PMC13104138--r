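#' Enumerate AUG-initiated candidate ORFs on a transcript sequence
#'
#' Finds, in all three frames, every AUG with an in-frame stop codon
#' (TAA/TAG/TGA) before the transcript end; AUGs without a downstream
#' in-frame stop are not emitted. Spans include the stop codon.
#'
#' @param seq uppercase DNA string (or a `TranscriptSequence`).
#' @param min_codons minimum ORF length in codons including start and
#'   stop (default 3: start + one amino acid + stop).
#' @return data.table `t_start`, `t_end` (0-based half-open span) and
#'   `stop_tpos` (start of the stop codon), sorted by `t_start`.
#' @export
enumerate_orfs <- function(seq, min_codons = 3L) {
  if (inherits(seq, "TranscriptSequence")) seq <- seq$seq
  empty <- data.table::data.table(t_start = integer(), t_end = integer(),
                                  stop_tpos = integer())
  n <- nchar(seq)
  if (n < 6L) return(empty)
  atg <- as.integer(gregexpr("ATG", seq, fixed = TRUE)[[1]])
  if (atg[1] == -1L) return(empty)
  atg <- atg - 1L  # 0-based
  stops <- sort(unlist(lapply(STOP_CODONS, function(s) {
    p <- as.integer(gregexpr(s, seq, fixed = TRUE)[[1]])
    if (p[1] == -1L) integer() else p - 1L
  })))
  if (length(stops) == 0L) return(empty)
  out <- vector("list", 3L)
  for (f in 0:2) {
    a <- atg[atg %% 3L == f]
    s <- stops[stops %% 3L == f & stops + 3L <= n]
    if (length(a) == 0L || length(s) == 0L) next
    # first in-frame stop at or after a + 3: smallest idx with
    # s[idx] >= a + 3, i.e. s[idx] > a + 2
    idx <- findInterval(a + 2L, s) + 1L
    ok <- idx <= length(s)
    out[[f + 1L]] <- data.table::data.table(t_start = a[ok],
                                            stop_tpos = s[idx[ok]])
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) return(empty)
  res[, t_end := stop_tpos + 3L]
  res <- res[(t_end - t_start) >= 3L * min_codons]
  data.table::setorder(res, t_start)
  res[, .(t_start, t_end, stop_tpos)]
}

#' Collapse same-stop ORFs to the longest
#'
#' Among candidate ORFs sharing a stop codon on the same transcript, only
#' the one with the most-upstream in-frame AUG (the longest) is retained.
#' Idempotent.
#'
#' @param candidates data.table with at least `t_start` and `stop_tpos`
#'   (plus `tx_id` when multiple transcripts are present).
#' @return filtered data.table, one row per (transcript, stop codon).
#' @export
collapse_by_stop <- function(candidates) {
  keys <- intersect(c("tx_id", "stop_tpos"), names(candidates))
  candidates[candidates[, .I[which.min(t_start)], by = keys]$V1]
}

#' Classify an ORF by the location of its AUG
#'
#' `five_prime_ORF` iff the AUG lies in the annotated 5' UTR (and the
#' span is not the mORF itself); `three_prime_ORF` iff the AUG lies in
#' the 3' UTR; `ncORF` iff the host transcript is noncoding/intergenic;
#' `mORF` iff the span equals the annotated CDS; `internal` (excluded
#' from the three classes) when the AUG falls inside the annotated CDS.
#'
#' @param orfs data.table with `tx_id`, `t_start`, `t_end`.
#' @param annot an [annotation_set()].
#' @return `orfs` with a `category` column added.
#' @export
classify_orf <- function(orfs, annot) {
  tx <- annot$transcripts[, .(tx_id, biotype, cds_tstart, cds_tend)]
  out <- tx[orfs, on = "tx_id"]
  out[, category := data.table::fcase(
    biotype != "protein_coding", "ncORF",
    t_start == cds_tstart & t_end == cds_tend, "mORF",
    t_start < cds_tstart, "five_prime_ORF",
    t_start >= cds_tend, "three_prime_ORF",
    default = "internal")]
  out[, c("biotype", "cds_tstart", "cds_tend") := NULL]
  out[]
}

#' Kozak context around an AUG
#'
#' Extracts the 11-nt window spanning positions -6..+5 (A of AUG = +1)
#' and applies the strong-context rule: A or G at -3 and G at +4.
#' Positions beyond the transcript edge are padded with `N`, which never
#' satisfies the rule.
#'
#' @param seq transcript DNA string (or `TranscriptSequence`).
#' @param aug_pos 0-based position of the A of the AUG.
#' @return list `context` (11-nt string) and `strong` (logical).
#' @export
kozak_strong <- function(seq, aug_pos) {
  if (inherits(seq, "TranscriptSequence")) seq <- seq$seq
  n <- nchar(seq)
  idx <- (aug_pos - 6L):(aug_pos + 4L)  # -6..-1, +1..+5
  base_at <- function(i) {
    if (i < 0L || i >= n) "N" else substr(seq, i + 1L, i + 1L)
  }
  ctx <- vapply(idx, base_at, character(1))
  minus3 <- base_at(aug_pos - 3L)
  plus4 <- base_at(aug_pos + 3L)
  list(context = paste(ctx, collapse = ""),
       strong = minus3 %in% c("A", "G") && plus4 == "G")
}

#' Discover and annotate candidate ORFs genome-wide
#'
#' Enumerates AUG..stop ORFs on every transcript, collapses same-stop
#' candidates to the longest, classifies them against the annotation,
#' and scores Kozak context. `internal` ORFs (AUG inside the annotated
#' CDS) and mORFs are kept in the table for bookkeeping but are not
#' candidates for UTR/noncoding translation.
#'
#' @param annot an [annotation_set()].
#' @param genome named character vector of chromosome sequences.
#' @param min_codons minimum ORF length in codons.
#' @return data.table with `orf_id`, `tx_id`, `gene_id`, `t_start`,
#'   `t_end`, `stop_tpos`, `category`, `kozak_context`, `kozak_strong`,
#'   `peptide`.
#' @export
discover_orfs <- function(annot, genome, min_codons = 3L) {
  tx_ids <- annot$transcripts$tx_id
  res <- vector("list", length(tx_ids))
  for (i in seq_along(tx_ids)) {
    ts <- spliced_sequence(annot, genome, tx_ids[i])
    cand <- enumerate_orfs(ts$seq, min_codons = min_codons)
    if (nrow(cand) == 0L) next
    cand[, tx_id := tx_ids[i]]
    cand <- collapse_by_stop(cand)
    koz <- lapply(cand$t_start, function(a) kozak_strong(ts$seq, a))
    cand[, kozak_context := vapply(koz, `[[`, character(1), "context")]
    cand[, kozak_strong := vapply(koz, `[[`, logical(1), "strong")]
    cand[, dna := substring(ts$seq, t_start + 1L, t_end)]
    res[[i]] <- cand
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) > 0L) {
    out[, peptide := translate_orf(dna)]
    out[, dna := NULL]
  }
  if (nrow(out) == 0L) {
    return(data.table::data.table(
      orf_id = character(), tx_id = character(), gene_id = character(),
      t_start = integer(), t_end = integer(), stop_tpos = integer(),
      category = character(), kozak_context = character(),
      kozak_strong = logical(), peptide = character()))
  }
  out <- classify_orf(out, annot)
  out <- annot$transcripts[, .(tx_id, gene_id)][out, on = "tx_id"]
  out[, orf_id := sprintf("orf%05d", seq_len(.N))]
  data.table::setcolorder(out, c("orf_id", "tx_id", "gene_id", "t_start",
                                 "t_end", "stop_tpos", "category"))
  out[]
}

# Transcript-coordinate intervals of annotated mORF CDS on the same
# strand, per candidate transcript position: returns data.table
# (tx_id, tpos, masked) for the given transcripts.
cds_mask_positions <- function(annot, tx_ids) {
  map <- tx_map(annot, tx_ids)
  cds <- annot$transcripts[, .(tx_id, chrom, strand)][annot$cds,
                                                      on = "tx_id"]
  if (nrow(cds) == 0L) {
    map[, masked := FALSE]
    return(map)
  }
  idx <- rep(seq_len(nrow(cds)), cds$end - cds$start)
  off <- sequence(cds$end - cds$start) - 1L
  cds_pos <- unique(data.table::data.table(
    chrom = cds$chrom[idx], strand = cds$strand[idx],
    gpos = cds$start[idx] + off))
  cds_pos[, masked := TRUE]
  map <- cds_pos[map, on = .(chrom, strand, gpos)]
  map[is.na(masked), masked := FALSE]
  map[]
}

#' Accept translated ORFs by 3-nt periodicity
#'
#' For every candidate ORF of the three UTR/noncoding classes, computes
#' frame statistics per stage (replicates pooled) over the codons that
#' do not overlap any annotated mORF CDS on the same strand, and accepts
#' the ORF iff [periodicity_pass()] holds in at least one stage. Also
#' records the ORF's per-stage translation level (RPKM over the ORF's
#' own span, using the stage's pooled Ribo library size).
#'
#' @param orfs candidate table from [discover_orfs()].
#' @param track P-site track with `sample` = `"<stage>_r<rep>"`.
#' @param annot an [annotation_set()].
#' @param stages character vector of stage names.
#' @param min_n,f0_min,alpha acceptance thresholds
#'   (see [periodicity_pass()]).
#' @param categories ORF classes subjected to the test.
#' @return list with `orfs` (candidate table gaining `accepted`,
#'   `n_pass_stages`, `best_f0`, `best_p`, `n_codons_unmasked`),
#'   `stage_stats` (per ORF x stage frame counts, `f0`, `p_value`,
#'   `pass`) and `orf_rpkm` (per ORF x stage translation level).
#' @export
accept_translated <- function(orfs, track, annot, stages,
                              min_n = 10L, f0_min = 0.6, alpha = 0.05,
                              categories = c("five_prime_ORF",
                                             "three_prime_ORF", "ncORF")) {
  cand <- orfs[category %in% categories]
  if (nrow(cand) == 0L) {
    return(list(orfs = cand, stage_stats = NULL, orf_rpkm = NULL))
  }
  map <- cds_mask_positions(annot, unique(cand$tx_id))
  tt <- track[map, on = .(chrom, strand, pos = gpos), nomatch = NULL]
  if (nrow(tt) > 0L) {
    tt[, c("stage", "rep_id") := data.table::tstrsplit(sample, "_r",
                                                       fixed = TRUE)]
  } else {
    tt[, `:=`(stage = character(), rep_id = character())]
  }
  tt <- tt[, .(count = sum(count)), by = .(tx_id, tpos, masked, stage)]

  # codon-level mask per ORF
  span <- cand[, .(orf_id, tx_id, t_start, t_end)]
  mpos <- map[masked == TRUE]
  masked_codons <- if (nrow(mpos) > 0L) {
    mj <- mpos[span, on = .(tx_id, tpos >= t_start, tpos < t_end),
               .(orf_id, tpos = x.tpos, t_start = i.t_start),
               nomatch = NULL]
    unique(mj[, .(orf_id, codon = (tpos - t_start) %/% 3L)])
  } else {
    data.table::data.table(orf_id = character(), codon = integer())
  }
  cand[, n_codons := (t_end - t_start) %/% 3L]
  nmask <- masked_codons[, .(n_masked = .N), by = orf_id]
  cand <- merge(cand, nmask, by = "orf_id", all.x = TRUE)
  cand[is.na(n_masked), n_masked := 0L]
  cand[, n_codons_unmasked := n_codons - n_masked]

  # P-sites within ORF spans, tagged with codon and frame
  hits <- tt[span, on = .(tx_id, tpos >= t_start, tpos < t_end),
             .(orf_id, stage, count, tpos = x.tpos, t_start = i.t_start),
             nomatch = NULL, allow.cartesian = TRUE]
  rpkm <- NULL
  stats <- NULL
  if (nrow(hits) > 0L) {
    hits[, `:=`(codon = (tpos - t_start) %/% 3L,
                frame = (tpos - t_start) %% 3L)]
    hits <- hits[!masked_codons, on = .(orf_id, codon)]
    stats <- data.table::dcast(
      hits[, .(n = sum(count)), by = .(orf_id, stage, frame)],
      orf_id + stage ~ frame, value.var = "n", fill = 0L)
    for (col in c("0", "1", "2")) {
      if (!col %in% names(stats)) stats[, (col) := 0L]
    }
    data.table::setnames(stats, c("0", "1", "2"), c("n0", "n1", "n2"))
    stats[, n := n0 + n1 + n2]
    stats[, f0 := ifelse(n > 0, n0 / n, NA_real_)]
    stats[, p_value := frame_binom_p(n0, n)]
    stats[, pass := periodicity_pass(.SD, min_n = min_n, f0_min = f0_min,
                                     alpha = alpha)]
  }
  acc <- if (!is.null(stats)) {
    stats[, .(n_pass_stages = sum(pass),
              best_f0 = f0[which.max(n)] %||% NA_real_,
              best_p = suppressWarnings(min(p_value, na.rm = TRUE))),
          by = orf_id]
  } else NULL
  if (!is.null(acc)) {
    cand <- merge(cand, acc, by = "orf_id", all.x = TRUE)
  } else {
    cand[, `:=`(n_pass_stages = 0L, best_f0 = NA_real_,
                best_p = NA_real_)]
  }
  cand[is.na(n_pass_stages), n_pass_stages := 0L]
  cand[, accepted := n_pass_stages >= 1L]

  # ORF translation level: RPKM over the full ORF span per stage
  libs <- data.table::copy(track)
  libs[, stage := data.table::tstrsplit(sample, "_r", fixed = TRUE)[[1]]]
  libs <- libs[, .(total = sum(count)), by = stage]
  full_hits <- tt[span, on = .(tx_id, tpos >= t_start, tpos < t_end),
                  .(orf_id, stage, count), nomatch = NULL,
                  allow.cartesian = TRUE]
  grid <- data.table::CJ(orf_id = cand$orf_id, stage = stages)
  cnt <- full_hits[, .(count = sum(count)), by = .(orf_id, stage)]
  rpkm <- merge(grid, cnt, by = c("orf_id", "stage"), all.x = TRUE)
  rpkm[is.na(count), count := 0L]
  rpkm <- merge(rpkm, cand[, .(orf_id, span_kb = (t_end - t_start) / 1000)],
                by = "orf_id")
  rpkm <- merge(rpkm, libs, by = "stage")
  rpkm[, value := 0]
  rpkm[total > 0, value := normalize_fpkm(count, span_kb, total / 1e6)]
  list(orfs = cand[], stage_stats = stats, orf_rpkm = rpkm[])
}

#' Genome-space blocks of ORF calls
#'
#' @param annot an [annotation_set()].
#' @param orfs data.table with `orf_id`, `tx_id`, `t_start`, `t_end`.
#' @return data.table `orf_id`, `chrom`, `strand`, `start`, `end`, one
#'   row per genome block (0-based half-open, genome order).
#' @export
orf_genome_blocks <- function(annot, orfs) {
  res <- lapply(seq_len(nrow(orfs)), function(i) {
    b <- tpos_blocks(annot, orfs$tx_id[i], orfs$t_start[i], orfs$t_end[i])
    tx <- annot$transcripts[tx_id == orfs$tx_id[i]]
    data.table::data.table(orf_id = orfs$orf_id[i], chrom = tx$chrom,
                           strand = tx$strand, start = b$start,
                           end = b$end)
  })
  data.table::rbindlist(res)
}
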