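test_that("ORF enumeration handles the canonical small cases", {
  r <- enumerate_orfs("CCATGGCGTAACC")
  expect_equal(nrow(r), 1L)
  expect_equal(r$t_start, 2L)
  expect_equal(r$t_end, 11L)
  expect_equal(translate_orf(substr("CCATGGCGTAACC", 3, 11)), "MA")
  expect_equal(nrow(enumerate_orfs("CCCCCCGGGTTT")), 0L)  # no ATG
  # minimal ORF (start + stop) is visible below the default length floor
  r2 <- enumerate_orfs("ATGTAA", min_codons = 2L)
  expect_equal(r2$t_start, 0L)
  expect_equal(r2$t_end, 6L)
  # an AUG without an in-frame stop is not emitted
  expect_equal(nrow(enumerate_orfs("ATGAAAAAA")), 0L)
})

test_that("fast scanner equals the brute-force regex oracle", {
  set.seed(17)
  for (i in 1:150) {
    s <- random_genome_string(sample(50:600, 1))
    fast <- enumerate_orfs(s)[, .(t_start, t_end)]
    data.table::setorder(fast, t_start, t_end)
    expect_identical(fast, orf_scan_oracle(s))
  }
})

test_that("same-stop collapsing keeps the most-upstream start", {
  cand <- data.table::data.table(
    tx_id = "t", t_start = c(2L, 8L, 20L), stop_tpos = c(20L, 20L, 40L),
    t_end = c(23L, 23L, 43L))
  col <- collapse_by_stop(cand)
  expect_equal(nrow(col), 2L)
  expect_equal(col[stop_tpos == 20L, t_start], 2L)
  expect_equal(col[stop_tpos == 40L, t_start], 20L)
  # idempotent
  expect_identical(collapse_by_stop(col), col)
  # unique (transcript, stop) pairs afterwards
  expect_equal(anyDuplicated(col[, .(tx_id, stop_tpos)]), 0L)
})

test_that("classification follows AUG position against the gene model", {
  a <- tiny_annotation()
  # txA: cds [10, 50) in transcript space (5'UTR 10 nt, 3'UTR 10 nt)
  orfs <- data.table::data.table(
    tx_id = c("txA", "txA", "txA", "txA", "nct"),
    t_start = c(0L, 10L, 20L, 50L, 5L),
    t_end = c(9L, 50L, 35L, 59L, 20L))
  cl <- classify_orf(orfs, a)
  expect_equal(cl$category, c("five_prime_ORF", "mORF", "internal",
                              "three_prime_ORF", "ncORF"))
})

test_that("Kozak strength needs A/G at -3 and G at +4", {
  # all 16 combinations of -3 and +4 bases
  for (m3 in c("A", "C", "G", "T")) {
    for (p4 in c("A", "C", "G", "T")) {
      s <- paste0("CCC", m3, "CC", "ATG", p4, "CCTAA")
      kz <- kozak_strong(s, 6L)
      expect_equal(kz$strong, m3 %in% c("A", "G") && p4 == "G",
                   info = paste(m3, p4))
    }
  }
  # context window is -6..+5 (11 nt)
  kz <- kozak_strong("CCCACCATGGCCTAA", 6L)
  expect_equal(nchar(kz$context), 11L)
  expect_equal(kz$context, "CCCACCATGGC")
  # AUG at position 0: no -3 base, padded with N, never strong
  kz0 <- kozak_strong("ATGGAATAA", 0L)
  expect_false(kz0$strong)
  expect_equal(substr(kz0$context, 1, 6), "NNNNNN")
})

test_that("ORFs with no P-sites anywhere are rejected", {
  sim <- small_sim()
  orfs <- discover_orfs(sim$annot, sim$genome)
  empty <- psite_track(data.table::data.table(
    sample = "S01_r1", chrom = names(sim$annot$chromosomes)[1],
    strand = "+", pos = 0L, count = 0L))
  acc <- accept_translated(orfs, empty, sim$annot,
                           sim$config$stage_names)
  expect_false(any(acc$orfs$accepted))
})

test_that("codons overlapping the mORF CDS are masked from the test", {
  # uORF overlapping the CDS start: only its UTR codons count
  a <- tiny_annotation()
  # txA 5'UTR is [0,10); build an ORF [4, 22) overlapping CDS at [10,22)
  orfs <- data.table::data.table(
    orf_id = "o1", tx_id = "txA", gene_id = "geneA",
    t_start = 4L, t_end = 22L, stop_tpos = 19L,
    category = "five_prime_ORF")
  map <- tx_map(a, "txA")
  # load frame-0 P-sites on every codon of the ORF
  tr <- psite_track(data.table::data.table(
    sample = "S1_r1", chrom = "chrT", strand = "+",
    pos = map[tpos %in% seq(4L, 21L, by = 3L), gpos],
    count = 30L))
  acc <- accept_translated(orfs, tr, a, "S1")
  # 6 codons total, codons 2..5 overlap the CDS -> 2 codons left
  expect_equal(acc$orfs$n_codons_unmasked, 2L)
  expect_equal(acc$stage_stats$n, 60L)  # only unmasked codons tallied
})

test_that("category calls are invariant under genome mirroring", {
  sim <- small_sim()
  a <- sim$annot
  # mirror: reverse-complement every chromosome, flip coordinates/strands
  L <- a$chromosomes
  flip <- function(dt) {
    dt <- data.table::copy(dt)
    dt[, c("start", "end") := .(L[chrom] - end, L[chrom] - start)]
    dt
  }
  genes2 <- flip(a$genes)[, strand := ifelse(strand == "+", "-", "+")]
  a2 <- annotation_set(
    chromosomes = L, genes = genes2,
    transcripts = a$transcripts[, .(tx_id, gene_id, biotype)],
    exons = flip(a$exons)[, .(tx_id, start, end)],
    cds = flip(a$transcripts[, .(tx_id, chrom)][a$cds, on = "tx_id"])[
      , .(tx_id, start, end)])
  genome2 <- vapply(sim$genome, revcomp, character(1))
  o1 <- discover_orfs(sim$annot, sim$genome)
  o2 <- discover_orfs(a2, genome2)
  expect_equal(table(o1$category), table(o2$category))
  # spans in transcript space are identical too
  k1 <- o1[order(tx_id, t_start, t_end), .(tx_id, t_start, t_end)]
  k2 <- o2[order(tx_id, t_start, t_end), .(tx_id, t_start, t_end)]
  expect_equal(k1, k2)
})

test_that("planted ORFs are recovered with correct categories", {
  sim <- small_sim()
  orfs <- discover_orfs(sim$annot, sim$genome)
  acc <- accept_translated(orfs, sim$ribo$track, sim$annot,
                           sim$config$stage_names)
  m <- merge(acc$orfs,
             sim$truth$orfs[, .(tx_id, stop_tpos, translated,
                                true_cat = category,
                                true_start = t_start)],
             by = c("tx_id", "stop_tpos"), all.x = TRUE)
  hits <- m[!is.na(translated) & translated == TRUE]
  expect_gt(mean(hits$accepted), 0.85)
  expect_true(all(m[accepted & translated %in% TRUE,
                    category == true_cat]))
  # collapsing preserved the planted start
  expect_true(all(hits$t_start == hits$true_start))
  # untranslated planted ORFs stay rejected
  expect_lt(mean(m[translated %in% FALSE, accepted]), 0.05)
})
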