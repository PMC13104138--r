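test_that("length histogram reports observed bins and window fractions", {
  tr <- psite_track(data.table::data.table(
    sample = "s", chrom = "c", strand = "+",
    pos = c(1L, 2L, 3L), read_length = c(28L, 28L, 29L),
    count = c(4L, 6L, 5L)))
  lh <- length_histogram(tr)
  expect_equal(lh$hist$read_length, c(28L, 29L))
  expect_equal(lh$hist$count, c(10L, 5L))
  expect_equal(lh$fraction_25_33, 1)
  # empty track -> empty histogram
  expect_equal(nrow(length_histogram(empty_track <- psite_track(
    data.table::data.table()))$hist), 0L)
  # missing lengths -> histogram unavailable, not zeroed
  tr2 <- psite_track(data.table::data.table(
    sample = "s", chrom = "c", strand = "+", pos = 1L,
    read_length = NA_integer_, count = 3L))
  expect_false(length_histogram(tr2)$available)
  # default simulation: essentially all mass within 25-33
  expect_gte(length_histogram(small_sim()$ribo$track)$fraction_25_33,
             0.95)
})

test_that("frame-0 binomial test matches binom.test exactly", {
  for (case in list(c(30L, 30L), c(10L, 30L), c(0L, 12L), c(45L, 60L))) {
    expect_equal(frame_binom_p(case[1], case[2]),
                 binom.test(case[1], case[2], 1 / 3,
                            alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
  expect_true(is.na(frame_binom_p(0L, 0L)))
})

test_that("frame statistics match a brute-force tally on a toy track", {
  a <- tiny_annotation()
  set.seed(31)
  # scatter counts over txA's region [10, 40) and txB
  tr <- psite_track(data.table::data.table(
    sample = "s", chrom = "chrT",
    strand = sample(c("+", "-"), 60, replace = TRUE),
    pos = sample(10:189, 60, replace = TRUE),
    read_length = 28L, count = sample(1:4, 60, replace = TRUE)))
  fs <- frame_stats(tr, a, "txA", 6L, 36L)
  oracle <- frame_tally_oracle(tr, a, "txA", 6L, 36L)
  expect_equal(c(fs$n0, fs$n1, fs$n2), oracle)
  expect_equal(fs$n, sum(oracle))
  # masked interval removes whole codons
  fs2 <- frame_stats(tr, a, "txA", 6L, 36L,
                     mask = data.table::data.table(t_start = 12L,
                                                   t_end = 18L))
  oracle2 <- frame_tally_oracle(tr, a, "txA", 6L, 36L,
                                masked_codons = 2:3)
  expect_equal(c(fs2$n0, fs2$n1, fs2$n2), oracle2)
  # minus-strand transcript works in transcript orientation
  fsB <- frame_stats(tr, a, "txB", 0L, 90L)
  oracleB <- frame_tally_oracle(tr, a, "txB", 0L, 90L)
  expect_equal(c(fsB$n0, fsB$n1, fsB$n2), oracleB)
})

test_that("extreme frame counts give the expected tail p-values", {
  a <- tiny_annotation()
  mk <- function(n0, n1, n2) {
    # place counts directly on txA frames 0/1/2 at codons 0..
    map <- tx_map(a, "txA")
    rows <- list()
    add <- function(f, n) {
      if (n == 0) return(NULL)
      data.table::data.table(sample = "s", chrom = "chrT", strand = "+",
                             pos = map[tpos == 6L + f, gpos],
                             read_length = 28L, count = n)
    }
    psite_track(data.table::rbindlist(
      Filter(Negate(is.null), list(add(0L, n0), add(1L, n1), add(2L, n2)))))
  }
  fs <- frame_stats(mk(30L, 0L, 0L), a, "txA", 6L, 36L)
  expect_equal(fs$f0, 1)
  expect_lt(fs$p_value, 1e-14)
  fs2 <- frame_stats(mk(10L, 10L, 10L), a, "txA", 6L, 36L)
  expect_equal(fs2$f0, 1 / 3)
  expect_gt(fs2$p_value, 0.4)
  fs3 <- frame_stats(mk(0L, 0L, 0L), a, "txA", 6L, 36L)
  expect_equal(fs3$n, 0L)
  expect_true(is.na(fs3$p_value))
})

test_that("the acceptance rule gates on n, f0 and alpha", {
  mk <- function(n, f0, p) data.table::data.table(n = n, f0 = f0,
                                                  p_value = p)
  expect_true(periodicity_pass(mk(30L, 0.9, 1e-9)))
  expect_false(periodicity_pass(mk(5L, 1.0, 1e-9)))    # below min_n
  expect_false(periodicity_pass(mk(300L, 0.55, 1e-12))) # f0 < 0.6
  expect_false(periodicity_pass(mk(30L, 0.7, 0.2)))     # p > alpha
  expect_equal(periodicity_pass(mk(c(30L, 5L), c(0.9, 0.9),
                                   c(1e-9, 1e-9))),
               c(TRUE, FALSE))
})

test_that("offsets are recovered from 5'-end placements", {
  # constructed case: all 28-mers with 5' ends exactly 12 nt upstream of
  # the CDS start of txA (tpos 10 -> 5' end at tpos -2 is outside; use
  # P-sites at start codon, 5' ends 12 upstream inside the transcript)
  a <- tiny_annotation()
  map <- tx_map(a, "txA")
  # txA cds_tstart = 10; 5' ends at tpos 10 - 12 not available, so use
  # geneB (cds_tstart = 10 as well on a 90 nt exon): place P-sites at
  # codons 4..6 of txB so 5' ends stay inside the transcript
  mapB <- tx_map(a, "txB")
  cds_t <- a$transcripts[tx_id == "txB", cds_tstart]
  psite_t <- cds_t + c(0L, 3L, 6L)
  g_5p <- mapB[tpos %in% (psite_t - 12L), gpos]
  pl <- psite_track(data.table::data.table(
    sample = "s", chrom = "chrT", strand = "-",
    pos = rep(g_5p, each = 20L), read_length = 28L, count = 1L))
  ap <- assign_psites(pl, a)
  expect_equal(ap$offsets[read_length == 28L, offset], 12L)
  expect_true(ap$offsets[read_length == 28L, estimated])
  # recovered P-sites sit at the intended transcript positions
  rec <- ap$track[mapB, on = .(chrom, strand, pos = gpos), nomatch = NULL]
  expect_setequal(rec$tpos, psite_t)
  # a length with no reads falls back to the default, flagged
  pl2 <- psite_track(rbind(pl, data.table::data.table(
    sample = "s", chrom = "chrT", strand = "+", pos = 300L,
    read_length = 33L, count = 1L)))
  ap2 <- assign_psites(pl2, a)
  expect_equal(ap2$offsets[read_length == 33L, offset], 12L)
  expect_false(ap2$offsets[read_length == 33L, estimated])
  expect_true(length(ap2$warning) > 0L)
})

test_that("raw-placement simulation round-trips through offset calling", {
  cfg <- sim_config(seed = 13L, n_genes = 25L, n_nc_transcripts = 5L,
                    orf_plan = list(n_five = 8L, n_three = 8L, n_nc = 3L),
                    psite_mode = "raw")
  sim <- simulate_dataset(cfg)
  ap <- assign_psites(sim$ribo$placements, sim$annot)
  est <- ap$offsets[n_reads >= 50L]
  expect_true(all(est$offset == 12L))
  key <- c("sample", "chrom", "strand", "pos", "read_length")
  expect_equal(data.table::setorderv(ap$track, key),
               data.table::setorderv(data.table::copy(sim$ribo$track),
                                     key))
})
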