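#' Footprint length histogram
#'
#' @param track a P-site track ([psite_track()]).
#' @return list with `hist` (data.table `read_length`, `count`),
#'   `fraction_25_33`, `fraction_25_30` (the two footprint windows
#'   reported by QC) and `available` (`FALSE` when the track carries no
#'   read lengths, in which case the histogram is marked unavailable
#'   rather than zeroed).
#' @export
length_histogram <- function(track) {
  if (nrow(track) == 0L) {
    return(list(hist = data.table::data.table(read_length = integer(),
                                              count = integer()),
                fraction_25_33 = NA_real_, fraction_25_30 = NA_real_,
                available = TRUE))
  }
  if (all(is.na(track$read_length))) {
    return(list(hist = NULL, fraction_25_33 = NA_real_,
                fraction_25_30 = NA_real_, available = FALSE))
  }
  h <- track[!is.na(read_length), .(count = sum(count)), by = read_length]
  data.table::setorder(h, read_length)
  tot <- sum(h$count)
  list(hist = h,
       fraction_25_33 = h[read_length >= 25 & read_length <= 33,
                          sum(count)] / tot,
       fraction_25_30 = h[read_length >= 25 & read_length <= 30,
                          sum(count)] / tot,
       available = TRUE)
}

#' One-sided binomial test for frame-0 enrichment
#'
#' Exact upper-tail p-value of observing at least `n0` frame-0 P-sites in
#' `n` trials under the null success probability 1/3 (no periodicity);
#' identical to `binom.test(n0, n, 1/3, alternative = "greater")` but
#' vectorized.
#'
#' @param n0 frame-0 counts.
#' @param n total counts.
#' @return p-values (`NA` where `n == 0`).
#' @export
frame_binom_p <- function(n0, n) {
  p <- stats::pbinom(n0 - 1L, n, 1 / 3, lower.tail = FALSE)
  p[n == 0L] <- NA_real_
  p
}

new_frame_stats <- function(region_id, n0, n1, n2) {
  n <- n0 + n1 + n2
  structure(list(region_id = region_id, n0 = n0, n1 = n1, n2 = n2, n = n,
                 f0 = if (n > 0L) n0 / n else NA_real_,
                 p_value = frame_binom_p(n0, n)),
            class = "FrameStats")
}

#' Per-frame P-site statistics for one ORF region
#'
#' Tallies P-sites over the codons of an ORF span on a transcript, with
#' frames defined relative to the region's own start codon (so nested or
#' overlapping ORFs are evaluated independently of the annotated reading
#' frame). Codons with any position inside `mask` (e.g. annotated mORF
#' CDS) are excluded entirely.
#'
#' @param track a P-site track (all samples pooled as given).
#' @param annot an [annotation_set()].
#' @param transcript_id host transcript.
#' @param t_start,t_end ORF span in transcript coordinates (0-based
#'   half-open, length a multiple of 3, stop codon included).
#' @param mask optional data.table of transcript-coordinate intervals
#'   (`t_start`, `t_end`) whose overlapping codons are excluded.
#' @return a `FrameStats` object: counts `n0`/`n1`/`n2`, total `n`, `f0`,
#'   and the upper-tail binomial `p_value` (`NA` when `n = 0`, e.g. a
#'   fully masked region).
#' @export
frame_stats <- function(track, annot, transcript_id, t_start, t_end,
                        mask = NULL) {
  assert_that((t_end - t_start) %% 3L == 0L,
              "ORF span must be a multiple of 3")
  map <- tx_map(annot, transcript_id)[tpos >= t_start & tpos < t_end]
  map[, codon := (tpos - t_start) %/% 3L]
  if (!is.null(mask) && nrow(mask) > 0L) {
    bad <- unique(unlist(lapply(seq_len(nrow(mask)), function(i) {
      map[tpos >= mask$t_start[i] & tpos < mask$t_end[i], codon]
    })))
    map <- map[!(codon %in% bad)]
  }
  tt <- track[map, on = .(chrom, strand, pos = gpos), nomatch = NULL]
  frames <- (tt$tpos - t_start) %% 3L
  cnt <- vapply(0:2, function(f) sum(tt$count[frames == f]), numeric(1))
  new_frame_stats(paste0(transcript_id, ":", t_start, "-", t_end),
                  as.integer(cnt[1]), as.integer(cnt[2]),
                  as.integer(cnt[3]))
}

#' @export
print.FrameStats <- function(x, ...) {
  cat(sprintf("FrameStats %s: n=%d (%d/%d/%d) f0=%.3f p=%.3g\n",
              x$region_id, x$n, x$n0, x$n1, x$n2, x$f0,
              x$p_value %||% NA_real_))
  invisible(x)
}

#' Periodicity acceptance rule
#'
#' A region passes iff `n >= min_n`, `f0 >= f0_min` and
#' `p_value <= alpha`. Defaults: at least 10 P-sites, frame-0 fraction at
#' least 0.6, alpha 0.05.
#'
#' @param stats a `FrameStats` object, or a data.frame/data.table with
#'   columns `n`, `f0`, `p_value` (vectorized).
#' @param min_n,f0_min,alpha thresholds.
#' @return logical (vector for tabular input).
#' @export
periodicity_pass <- function(stats, min_n = 10L, f0_min = 0.6,
                             alpha = 0.05) {
  if (inherits(stats, "FrameStats")) {
    stats <- data.table::data.table(n = stats$n, f0 = stats$f0,
                                    p_value = stats$p_value)
  }
  with(stats, n >= min_n & !is.na(f0) & f0 >= f0_min &
         !is.na(p_value) & p_value <= alpha)
}

#' Calibrate P-site offsets and convert 5'-end placements to P-sites
#'
#' For each footprint length L, the offset is the modal distance from the
#' read 5' end to an annotated CDS start, over a metagene window spanning
#' 40 nt upstream to 10 nt downstream of the start (ties broken toward
#' `default_offset`). P-sites are then `5' end + offset(L)`,
#' strand-aware. Lengths without at least `min_reads` reads in the
#' window fall back to `default_offset` and are flagged, as is the whole
#' calibration when no annotated start is covered.
#'
#' @param placements 5'-end read placement track (same shape as a P-site
#'   track; `pos` is the genomic position of the read 5' end).
#' @param annot an [annotation_set()] with coding transcripts.
#' @param default_offset fallback offset in nt (12 by default).
#' @param min_reads minimum metagene reads to estimate a length's offset.
#' @param window metagene window around the CDS start,
#'   `c(upstream, downstream)` in nt.
#' @return list with `track` (the offset-corrected P-site track),
#'   `offsets` (data.table `read_length`, `offset`, `n_reads`,
#'   `estimated`) and `warning` (character, zero length when clean).
#' @export
assign_psites <- function(placements, annot, default_offset = 12L,
                          min_reads = 20L, window = c(40L, 10L)) {
  coding <- annot$transcripts[biotype == "protein_coding" &
                              !is.na(cds_tstart)]
  warn <- character()
  lens_obs <- sort(unique(placements$read_length))
  offsets <- data.table::data.table(read_length = lens_obs,
                                    offset = default_offset,
                                    n_reads = 0L, estimated = FALSE)
  if (nrow(coding) > 0L && nrow(placements) > 0L) {
    map <- tx_map(annot, coding$tx_id)
    map <- coding[, .(tx_id, cds_tstart)][map, on = "tx_id"]
    map[, d := cds_tstart - tpos]  # 5'end at tpos -> distance to start
    meta <- map[d >= -window[2] & d <= window[1]]
    hits <- placements[meta, on = .(chrom, strand, pos = gpos),
                       nomatch = NULL]
    if (nrow(hits) == 0L) {
      warn <- c(warn, "no annotated CDS starts covered; using default offset")
    } else {
      est <- hits[!is.na(read_length),
                  .(offset = stat_mode(rep(d[d >= 0L], count[d >= 0L]),
                                       prefer = default_offset),
                    n_reads = sum(count)), by = read_length]
      est[is.na(offset), offset := default_offset]
      offsets[est, on = "read_length",
              `:=`(n_reads = i.n_reads,
                   offset = ifelse(i.n_reads >= min_reads, i.offset,
                                   default_offset),
                   estimated = i.n_reads >= min_reads)]
    }
  } else if (nrow(coding) == 0L) {
    warn <- c(warn, "annotation has no coding transcripts; using default offset")
  }
  if (any(!offsets$estimated)) {
    warn <- c(warn, sprintf(
      "offset fell back to default %d for length(s): %s", default_offset,
      paste(offsets[estimated == FALSE, read_length], collapse = ", ")))
  }
  track <- data.table::copy(placements)
  track[offsets, on = "read_length", offset_nt := i.offset]
  track[is.na(offset_nt), offset_nt := default_offset]
  track[, pos := ifelse(strand == "+", pos + offset_nt, pos - offset_nt)]
  track[, offset_nt := NULL]
  list(track = psite_track(track), offsets = offsets, warning = warn)
}
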