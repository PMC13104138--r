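# Shared fixtures and independent oracles, built in code at test time.

# Hand-built two-gene annotation on a 400 bp chromosome:
#  geneA (+): exons [10,40) and [50,80); CDS [20,70) within exons ->
#    5'UTR exonic length 10, CDS spliced length 40 (not used for
#    translation), 3'UTR exonic length 10.
#  geneB (-): single exon [100,190); CDS [110,170).
#  ncg (+): noncoding single exon [250,330).
tiny_annotation <- function(chrom_len = 400L) {
  annotation_set(
    chromosomes = c(chrT = chrom_len),
    genes = data.table::data.table(
      gene_id = c("geneA", "geneB", "ncg"),
      chrom = "chrT",
      strand = c("+", "-", "+"),
      start = c(10L, 100L, 250L),
      end = c(80L, 190L, 330L)),
    transcripts = data.table::data.table(
      tx_id = c("txA", "txB", "nct"),
      gene_id = c("geneA", "geneB", "ncg"),
      biotype = c("protein_coding", "protein_coding", "noncoding")),
    exons = data.table::data.table(
      tx_id = c("txA", "txA", "txB", "nct"),
      start = c(10L, 50L, 100L, 250L),
      end = c(40L, 80L, 190L, 330L)),
    cds = data.table::data.table(
      tx_id = c("txA", "txA", "txB"),
      start = c(20L, 50L, 110L),
      end = c(40L, 70L, 170L)))
}

random_genome_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small cached simulation shared across test files (expensive to build).
small_sim_cache <- new.env()
small_sim <- function() {
  if (is.null(small_sim_cache$sim)) {
    cfg <- sim_config(seed = 42L, n_genes = 60L, n_nc_transcripts = 12L,
                      orf_plan = list(n_five = 20L, n_three = 20L,
                                      n_nc = 8L))
    small_sim_cache$sim <- simulate_dataset(cfg)
  }
  small_sim_cache$sim
}

# Full default-scale simulation (the study-design defaults), cached.
default_sim <- function() {
  if (is.null(small_sim_cache$default)) {
    small_sim_cache$default <- simulate_dataset(sim_config(seed = 101L))
  }
  small_sim_cache$default
}

# Five-gene single-stage fixture with hand-computed FPKM/RPKM/TE.
# RNA total 1000 fragments (0.001 M); Ribo total 500 (0.0005 M).
# FPKM_i = count_i / exon_kb_i / 0.001 ; RPKM_i = count_i / cds_kb_i / 5e-4
five_gene_fixture <- function() {
  annot <- annotation_set(
    chromosomes = c(c1 = 20000L),
    genes = data.table::data.table(
      gene_id = paste0("g", 1:5), chrom = "c1", strand = "+",
      start = seq(0L, 16000L, by = 4000L),
      end = seq(0L, 16000L, by = 4000L) + 2000L),
    transcripts = data.table::data.table(
      tx_id = paste0("t", 1:5), gene_id = paste0("g", 1:5),
      biotype = "protein_coding"),
    exons = data.table::data.table(
      tx_id = paste0("t", 1:5),
      start = seq(0L, 16000L, by = 4000L),
      end = seq(0L, 16000L, by = 4000L) + c(2000L, 1000L, 500L, 2000L,
                                            1000L)),
    cds = data.table::data.table(
      tx_id = paste0("t", 1:5),
      start = seq(0L, 16000L, by = 4000L),
      end = seq(0L, 16000L, by = 4000L) + c(600L, 300L, 300L, 1500L,
                                            900L)))
  list(
    annot = annot,
    rna = data.table::data.table(
      gene_id = paste0("g", 1:5), stage = "S1", rep = 1L,
      count = c(400L, 200L, 100L, 200L, 100L)),
    ribo = data.table::data.table(
      gene_id = paste0("g", 1:5), stage = "S1", rep = 1L,
      count = c(150L, 60L, 0L, 150L, 140L)),
    fpkm = c(400 / 2, 200 / 1, 100 / 0.5, 200 / 2, 100 / 1) / 0.001,
    rpkm = c(150 / 0.6, 60 / 0.3, 0, 150 / 1.5, 140 / 0.9) / 5e-4)
}

# --- independent oracles ----------------------------------------------

# Brute-force three-frame regex ORF scan (overlapping matches via
# lookahead), returning 0-based half-open spans including the stop.
orf_scan_oracle <- function(seq, min_codons = 3L) {
  hits <- list()
  m <- gregexpr("(?=(ATG(?:[ACGT]{3})*?(?:TAA|TAG|TGA)))", seq,
                perl = TRUE)[[1]]
  if (m[1] != -1L) {
    starts <- as.integer(m) - 1L
    lens <- attr(m, "capture.length")[, 1]
    keep <- lens >= 3L * min_codons
    hits <- data.table::data.table(t_start = starts[keep],
                                   t_end = starts[keep] + lens[keep])
  } else {
    hits <- data.table::data.table(t_start = integer(), t_end = integer())
  }
  data.table::setorder(hits, t_start, t_end)
  hits[]
}

# Textbook Pearson correlation from first principles.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Two-pass population variance.
pop_var_oracle <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / length(x)
}

# Exhaustive hypergeometric upper tail via binomial coefficients.
hyper_tail_oracle <- function(k, K, N, n) {
  js <- k:min(K, n)
  js <- js[js >= max(0L, n - (N - K))]
  if (length(js) == 0L) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Sum a P-site track's frame tally over a transcript region the slow way.
frame_tally_oracle <- function(track, annot, tx, t0, t1,
                               masked_codons = integer()) {
  map <- tx_map(annot, tx)
  counts <- c(0L, 0L, 0L)
  for (tp in t0:(t1 - 1L)) {
    codon <- (tp - t0) %/% 3L
    if (codon %in% masked_codons) next
    g <- map[tpos == tp]
    rows <- track[chrom == g$chrom & strand == g$strand & pos == g$gpos]
    f <- (tp - t0) %% 3L
    counts[f + 1L] <- counts[f + 1L] + sum(rows$count)
  }
  counts
}
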