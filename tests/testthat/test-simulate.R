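test_that("generator is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 5L, n_genes = 15L, n_nc_transcripts = 4L,
                    orf_plan = list(n_five = 4L, n_three = 4L, n_nc = 2L))
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  write_genome(g1$genome, file.path(d1, "g.fa"))
  write_genome(g2$genome, file.path(d2, "g.fa"))
  write_gff3(g1$annot, file.path(d1, "a.gff3"))
  write_gff3(g2$annot, file.path(d2, "a.gff3"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "a.gff3")),
                   readLines(file.path(d2, "a.gff3")))
  expect_identical(g1$truth$orfs, g2$truth$orfs)
})

test_that("ORF-free plan yields only mORF structure", {
  cfg <- sim_config(seed = 3L, n_genes = 10L, n_nc_transcripts = 2L,
                    orf_plan = list(n_five = 0L, n_three = 0L, n_nc = 0L))
  g <- generate_genome(cfg)
  expect_equal(nrow(g$truth$orfs), 0L)
  expect_equal(nrow(g$annot$cds[, .N, by = tx_id]), 10L)
})

test_that("planted ORFs live in their advertised regions", {
  sim <- small_sim()
  tx <- sim$annot$transcripts
  orfs <- merge(sim$truth$orfs, tx, by = "tx_id")
  o5 <- orfs[category == "five_prime_ORF"]
  expect_true(all(o5$t_end <= o5$cds_tstart))
  o3 <- orfs[category == "three_prime_ORF"]
  # stop codon of a planted 3' ORF lies in the annotated 3' UTR
  expect_true(all(o3$t_start >= o3$cds_tend))
  expect_true(all(o3$stop_tpos >= o3$cds_tend &
                    o3$stop_tpos + 3L <= o3$tx_len))
  onc <- orfs[category == "ncORF"]
  expect_true(all(onc$t_end <= onc$tx_len))
  # planted spans are AUG..stop by construction
  for (i in seq_len(min(10L, nrow(orfs)))) {
    ts <- spliced_sequence(sim$annot, sim$genome, orfs$tx_id[i])
    dna <- substr(ts$seq, orfs$t_start[i] + 1L, orfs$t_end[i])
    expect_equal(substr(dna, 1, 3), "ATG")
    expect_true(substr(dna, nchar(dna) - 2, nchar(dna)) %in%
                  c("TAA", "TAG", "TGA"))
  }
})

test_that("planted Kozak context matches the truth flag", {
  sim <- small_sim()
  orfs <- sim$truth$orfs
  for (i in seq_len(nrow(orfs))) {
    ts <- spliced_sequence(sim$annot, sim$genome, orfs$tx_id[i])
    kz <- kozak_strong(ts, orfs$t_start[i])
    expect_equal(kz$strong, orfs$kozak_strong[i])
  }
})

test_that("RNA counts scale with abundance and depth", {
  cfg <- sim_config(seed = 9L, n_genes = 400L, n_nc_transcripts = 0L,
                    orf_plan = list(n_five = 0L, n_three = 0L, n_nc = 0L),
                    n_stages = 2L, stage_names = c("S1", "S2"),
                    phase_map = c("PI", "PI"))
  g <- generate_genome(cfg)
  # zero abundance -> zero counts, always
  tr0 <- data.table::copy(g$truth)
  tr0$genes[, abundance := 0]
  r0 <- simulate_rna(cfg, tr0)
  expect_true(all(r0$counts$count == 0L))
  # doubling depth doubles expected totals (within 3 sd of the Poisson sum)
  r1 <- simulate_rna(cfg, g$truth)
  cfg2 <- cfg; cfg2$rna_depth <- cfg$rna_depth * 2
  r2 <- simulate_rna(cfg2, g$truth)
  t1 <- sum(r1$counts$count); t2 <- sum(r2$counts$count)
  expect_lt(abs(t2 - 2 * t1), 3 * sqrt(4 * t1 + t2))
})

test_that("replicates are highly correlated at default depth", {
  sim <- small_sim()
  rc <- data.table::dcast(sim$rna$counts, gene_id + stage ~ rep,
                          value.var = "count")
  expect_gt(cor(log2(rc$`1` + 1), log2(rc$`2` + 1)), 0.96)
})

test_that("P-site frames follow the configured frame probabilities", {
  base <- list(seed = 21L, n_genes = 12L, n_nc_transcripts = 2L,
               orf_plan = list(n_five = 4L, n_three = 4L, n_nc = 2L,
                               translated_fraction = 1),
               background_rate = 0)
  # p0 = 1: every P-site in frame 0 of its unit
  cfg <- do.call(sim_config, c(base, list(frame_probs = c(1, 0, 0),
                                          init_peak_weight = 1)))
  g <- generate_genome(cfg)
  rb <- simulate_ribo(cfg, g$truth, g$annot)
  map <- tx_map(g$annot)
  tt <- rb$track[map, on = .(chrom, strand, pos = gpos), nomatch = NULL]
  cds <- g$annot$transcripts[!is.na(cds_tstart),
                             .(tx_id, cds_tstart, cds_tend)]
  inc <- tt[cds, on = "tx_id", nomatch = NULL][
    tpos >= cds_tstart & tpos < cds_tend]
  expect_true(all((inc$tpos - inc$cds_tstart) %% 3L == 0L))

  # default p0 = 0.75: pooled planted translated ORFs hit f0 within 0.05
  sim <- small_sim()
  omap <- tx_map(sim$annot, unique(sim$truth$orfs$tx_id))
  t2 <- sim$ribo$track[omap, on = .(chrom, strand, pos = gpos),
                       nomatch = NULL]
  frames <- function(otab) {
    h <- t2[otab, on = .(tx_id, tpos >= t_start, tpos < t_end),
            .(count, f = (x.tpos - i.t_start) %% 3L), nomatch = NULL]
    h[, .(n = sum(count)), keyby = f]$n
  }
  ftr <- frames(sim$truth$orfs[translated == TRUE])
  expect_gt(sum(ftr), 200)
  expect_lt(abs(ftr[1] / sum(ftr) - 0.75), 0.05)
  # untranslated planted ORFs see only uniform-frame background
  fun <- frames(sim$truth$orfs[translated == FALSE])
  if (sum(fun) >= 60) {
    expect_lt(max(abs(fun / sum(fun) - 1 / 3)),
              4 * sqrt((1 / 3) * (2 / 3) / sum(fun)))
  }
})

test_that("quantification recovers true TE on simulated data", {
  sim <- small_sim()
  cfg <- sim$config
  expr <- quantify_expression(sim$annot, sim$rna$counts, sim$ribo$track,
                              cfg$stage_names)
  te <- compute_te(expr)
  tt <- sim$truth$genes[, .(te_true = mean(te_true)), by = gene_id]
  est <- rowMeans(te$te)[tt$gene_id]
  expect_gt(cor(tt$te_true, est), 0.9)
  # near-unbiased: median ratio within [0.8, 1.25] for expressed genes
  fpkm_ok <- rowMeans(expr$rna)[tt$gene_id] >= 1
  expect_gt(median((est / tt$te_true)[fpkm_ok]), 0.8)
  expect_lt(median((est / tt$te_true)[fpkm_ok]), 1.25)
})

test_that("variation matrices carry the requested inflation", {
  set.seed(1)
  vm <- simulate_variation_matrices(n_genes = 5000L, inflation = 0.5)
  lv_rna <- apply(log2(vm$rna), 2, var)
  lv_ribo <- apply(log2(vm$ribo), 2, var)
  expect_lt(abs(mean(lv_ribo / lv_rna) - 1.5), 0.1)
})
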