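test_that("peptide matching is exact substring search with records", {
  orfs <- c(o1 = "MMARKQ", o2 = "MSTARKLESS")
  m <- match_peptides("MARK", orfs, min_len = 4L)
  expect_equal(m$matches$orf_id, "o1")
  expect_equal(m$matches$offset, 1L)
  # all matching ORFs are reported
  m2 <- match_peptides("ARK", orfs, min_len = 3L)
  expect_setequal(m2$matches$orf_id, c("o1", "o2"))
  # short peptides are skipped with a record, not dropped silently
  m3 <- match_peptides(c("MARKQ", "MAR"), orfs, min_len = 5L)
  expect_equal(m3$skipped$peptide, "MAR")
  expect_equal(nrow(m3$matches), 1L)
  # I/L equivalence is opt-in
  orfs2 <- c(o3 = "MKILK")
  expect_equal(nrow(match_peptides("KLLK", orfs2, min_len = 4L)$matches),
               0L)
  expect_equal(
    match_peptides("KLLK", orfs2, min_len = 4L,
                   il_equivalent = TRUE)$matches$orf_id, "o3")
})

test_that("peptide matching equals a sliding-window oracle", {
  set.seed(37)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  orfs <- stats::setNames(
    vapply(1:8, function(i) paste(sample(aas, 60, TRUE), collapse = ""),
           character(1)), paste0("o", 1:8))
  peps <- c(vapply(1:10, function(i) {
    src <- sample(orfs, 1)
    at <- sample(1:50, 1)
    substr(src, at, at + sample(7:12, 1))
  }, character(1)),
  vapply(1:5, function(i) paste(sample(aas, 9, TRUE), collapse = ""),
         character(1)))
  got <- match_peptides(peps, orfs)$matches
  oracle <- data.table::rbindlist(lapply(peps, function(p) {
    hits <- list()
    if (nchar(p) >= 7L) {
      for (oid in names(orfs)) {
        s <- orfs[[oid]]
        for (off in 0:(nchar(s) - nchar(p))) {
          if (substr(s, off + 1, off + nchar(p)) == p) {
            hits[[length(hits) + 1L]] <- data.table::data.table(
              peptide = p, orf_id = oid, offset = off)
          }
        }
      }
    }
    data.table::rbindlist(hits)
  }))
  key <- c("peptide", "orf_id", "offset")
  expect_equal(data.table::setorderv(got, key),
               data.table::setorderv(oracle, key))
})

test_that("simulated decoy peptides do not match accepted ORFs", {
  sim <- small_sim()
  orfs <- discover_orfs(sim$annot, sim$genome)
  acc <- accept_translated(orfs, sim$ribo$track, sim$annot,
                           sim$config$stage_names)
  accepted <- acc$orfs[accepted == TRUE]
  mp <- match_peptides(sim$peptides,
                       stats::setNames(accepted$peptide,
                                       accepted$orf_id))
  dec <- sim$peptides[decoy == TRUE, peptide]
  expect_equal(sum(mp$matches$peptide %in% dec), 0L)
  # most true peptides of accepted ORFs match their source
  truth_pep <- sim$peptides[decoy == FALSE]
  matched <- truth_pep$source_orf %in%
    sim$truth$orfs[tx_id %in% accepted$tx_id][
      , orf_id]  # source planted ids of accepted hosts
  expect_gt(nrow(mp$matches), 0L)
})

test_that("isoform support demands containment, strand and frame", {
  # host: plus-strand two-exon transcript; ORF crosses the junction
  host <- annotation_set(
    chromosomes = c(c1 = 500L),
    genes = data.table::data.table(gene_id = "g", chrom = "c1",
                                   strand = "+", start = 0L, end = 300L),
    transcripts = data.table::data.table(tx_id = "t", gene_id = "g",
                                         biotype = "noncoding"),
    exons = data.table::data.table(tx_id = "t", start = c(0L, 200L),
                                   end = c(100L, 300L)))
  orfs <- data.table::data.table(orf_id = "o1", tx_id = "t",
                                 t_start = 80L, t_end = 120L)
  iso_of <- function(exons, strand = "+") {
    annotation_set(
      chromosomes = c(c1 = 500L),
      genes = data.table::data.table(gene_id = "ig", chrom = "c1",
                                     strand = strand, start = 0L,
                                     end = 400L),
      transcripts = data.table::data.table(tx_id = "it", gene_id = "ig",
                                           biotype = "noncoding"),
      exons = data.table::data.table(tx_id = "it", start = exons$start,
                                     end = exons$end))
  }
  # same junction -> supported
  s1 <- isoform_support(orfs, host,
                        iso_of(data.table::data.table(
                          start = c(50L, 200L), end = c(100L, 260L))))
  expect_true(s1$supported)
  # junction absent (single exon spanning the intron) -> frame broken
  s2 <- isoform_support(orfs, host,
                        iso_of(data.table::data.table(start = 40L,
                                                      end = 260L)))
  expect_true(s2$contained)
  expect_false(s2$frame_intact)
  expect_false(s2$supported)
  # opposite strand -> unsupported regardless of overlap
  s3 <- isoform_support(orfs, host,
                        iso_of(data.table::data.table(
                          start = c(50L, 200L), end = c(100L, 260L)),
                          strand = "-"))
  expect_false(s3$supported)
  # partial containment -> unsupported
  s4 <- isoform_support(orfs, host,
                        iso_of(data.table::data.table(start = 90L,
                                                      end = 110L)))
  expect_false(any(s4$supported))
  # assembly mismatch is a hard error
  iso_bad <- iso_of(data.table::data.table(start = 1L, end = 10L))
  names(iso_bad$chromosomes) <- "cX"
  iso_bad$genes[, chrom := "cX"]
  iso_bad$exons[, chrom := "cX"]
  iso_bad$transcripts[, chrom := "cX"]
  expect_error(isoform_support(orfs, host, iso_bad), "mismatch")
})

test_that("simulator-backed isoforms are found with perfect accuracy", {
  sim <- small_sim()
  orfs <- discover_orfs(sim$annot, sim$genome)
  acc <- accept_translated(orfs, sim$ribo$track, sim$annot,
                           sim$config$stage_names)
  accepted <- acc$orfs[accepted == TRUE]
  truth <- sim$truth$orfs
  m <- merge(accepted, truth[, .(tx_id, stop_tpos, isoform_backed)],
             by = c("tx_id", "stop_tpos"), all.x = TRUE)
  expect_true(any(m$isoform_backed %in% TRUE))
  iso <- isoform_support(accepted, sim$annot, sim$isoforms)
  supported_ids <- unique(iso[supported == TRUE, orf_id])
  backed <- m[isoform_backed %in% TRUE, orf_id]
  not_backed <- m[!(isoform_backed %in% TRUE), orf_id]
  expect_true(all(backed %in% supported_ids))   # sensitivity 1
  expect_equal(sum(not_backed %in% supported_ids), 0L)  # specificity 1
})
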