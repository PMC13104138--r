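test_that("GFF3 1-based coordinates map to 0-based half-open internals", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrT 1 100",
    "chrT\tsrc\tgene\t1\t9\t.\t+\t.\tID=g1",
    "chrT\tsrc\tmRNA\t1\t9\t.\t+\t.\tID=t1;Parent=g1",
    "chrT\tsrc\texon\t1\t9\t.\t+\t.\tParent=t1",
    "chrT\tsrc\tCDS\t1\t9\t.\t+\t0\tParent=t1"), gff)
  a <- read_gff3(gff)
  expect_equal(a$genes$start, 0L)
  expect_equal(a$genes$end, 9L)
  expect_equal(unname(a$chromosomes["chrT"]), 100L)
})

test_that("UTR extents are inferred from exon/CDS structure", {
  # transcript with exons 1..30 and 41..70, CDS 11..60 (1-based GFF3):
  # exonic 5'UTR = 10 nt, exonic 3'UTR = 10 nt, spliced length 60
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chrT 1 100",
    "chrT\tsrc\tgene\t1\t70\t.\t+\t.\tID=g1",
    "chrT\tsrc\tmRNA\t1\t70\t.\t+\t.\tID=t1;Parent=g1",
    "chrT\tsrc\texon\t1\t30\t.\t+\t.\tParent=t1",
    "chrT\tsrc\texon\t41\t70\t.\t+\t.\tParent=t1",
    "chrT\tsrc\tCDS\t11\t30\t.\t+\t0\tParent=t1",
    "chrT\tsrc\tCDS\t41\t60\t.\t+\t2\tParent=t1"), gff)
  a <- read_gff3(gff)
  tx <- a$transcripts[tx_id == "t1"]
  expect_equal(tx$tx_len, 60L)
  expect_equal(tx$cds_tstart, 10L)   # 5'UTR = [0, 10)
  expect_equal(tx$cds_tend, 50L)     # 3'UTR = [50, 60)
  expect_equal(tx$cds_len, 40L)
  # 5'UTR + CDS + 3'UTR partitions the spliced transcript
  expect_equal(tx$cds_tstart + tx$cds_len + (tx$tx_len - tx$cds_tend),
               tx$tx_len)
})

test_that("minus-strand exons are ranked 5' to 3'", {
  a <- tiny_annotation()
  exB <- a$exons[tx_id == "txB"]
  expect_equal(exB$exon_rank, 1L)
  # two-exon minus-strand case: rank 1 must be the genome-rightmost exon
  a2 <- annotation_set(
    chromosomes = c(c1 = 1000L),
    genes = data.table::data.table(gene_id = "g", chrom = "c1",
                                   strand = "-", start = 0L, end = 500L),
    transcripts = data.table::data.table(tx_id = "t", gene_id = "g",
                                         biotype = "noncoding"),
    exons = data.table::data.table(tx_id = "t", start = c(0L, 300L),
                                   end = c(100L, 500L)))
  ex <- a2$exons[order(exon_rank)]
  expect_equal(ex$start, c(300L, 0L))
})

test_that("CDS length violations are flagged, not silently accepted", {
  a <- annotation_set(
    chromosomes = c(c1 = 100L),
    genes = data.table::data.table(gene_id = "g", chrom = "c1",
                                   strand = "+", start = 0L, end = 50L),
    transcripts = data.table::data.table(tx_id = "t", gene_id = "g",
                                         biotype = "protein_coding"),
    exons = data.table::data.table(tx_id = "t", start = 0L, end = 50L),
    cds = data.table::data.table(tx_id = "t", start = 10L, end = 21L))
  expect_false(a$transcripts$cds_len_ok)
  expect_true(tiny_annotation()$transcripts[tx_id == "txB", cds_len_ok])
})

test_that("structural errors are hard errors naming the offender", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\tsrc\tgene\t1\t50\t.\t+\t.\tID=g1",
    "chrT\tsrc\tmRNA\t1\t50\t.\t+\t.\tID=t1;Parent=gMISSING",
    "chrT\tsrc\texon\t1\t50\t.\t+\t.\tParent=t1"), gff)
  expect_error(read_gff3(gff), "t1")
  # CDS outside exons
  expect_error(annotation_set(
    chromosomes = c(c1 = 100L),
    genes = data.table::data.table(gene_id = "g", chrom = "c1",
                                   strand = "+", start = 0L, end = 60L),
    transcripts = data.table::data.table(tx_id = "t", gene_id = "g",
                                         biotype = "protein_coding"),
    exons = data.table::data.table(tx_id = "t", start = 0L, end = 30L),
    cds = data.table::data.table(tx_id = "t", start = 20L, end = 40L)),
    "outside exons")
})

test_that("spliced sequences follow strand and splicing", {
  a <- tiny_annotation()
  set.seed(11)
  genome <- c(chrT = random_genome_string(400))
  ssA <- spliced_sequence(a, genome, "txA")
  expect_equal(nchar(ssA$seq), 60L)
  expect_equal(ssA$seq, paste0(substr(genome, 11, 40),
                               substr(genome, 51, 80)))
  # minus strand reverse complements
  ssB <- spliced_sequence(a, genome, "txB")
  expect_equal(ssB$seq, unname(revcomp(substr(genome, 101, 190))))
  # position maps round-trip: genome position of tpos i maps back
  map <- tx_map(a, "txB")
  expect_equal(map$tpos, seq_len(90L) - 1L)
  expect_equal(map$gpos, 189:100)
  # two exons "AAA" and "TTT" splice to "AAATTT"
  g2 <- c(c1 = "GGAAAGGTTTGG")
  a2 <- annotation_set(
    chromosomes = c(c1 = 12L),
    genes = data.table::data.table(gene_id = "g", chrom = "c1",
                                   strand = "+", start = 2L, end = 10L),
    transcripts = data.table::data.table(tx_id = "t", gene_id = "g",
                                         biotype = "noncoding"),
    exons = data.table::data.table(tx_id = "t", start = c(2L, 7L),
                                   end = c(5L, 10L)))
  expect_equal(spliced_sequence(a2, g2, "t")$seq, "AAATTT")
  # exon beyond chromosome end in FASTA is a hard error
  expect_error(spliced_sequence(a, c(chrT = "ACGT"), "txA"),
               "chromosome length")
})

test_that("GFF3 round-trip reproduces coordinates exactly", {
  sim <- small_sim()
  f1 <- tempfile(fileext = ".gff3")
  f2 <- tempfile(fileext = ".gff3")
  write_gff3(sim$annot, f1)
  a2 <- read_gff3(f1)
  write_gff3(a2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(a2$exons[order(tx_id, start), .(tx_id, start, end)],
               sim$annot$exons[order(tx_id, start), .(tx_id, start, end)])
  expect_equal(a2$cds[order(tx_id, start)],
               sim$annot$cds[order(tx_id, start)])
})

test_that("UTR + CDS + UTR partitions every coding transcript", {
  tx <- small_sim()$annot$transcripts[biotype == "protein_coding"]
  expect_true(all(tx$cds_tstart + tx$cds_len +
                    (tx$tx_len - tx$cds_tend) == tx$tx_len))
  expect_true(all(tx$cds_len_ok))
})

test_that("P-site track reading aggregates, tolerates empty, validates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tstrand\tcount\tsample\tread_length",
               "c1\t10\t+\t3\ts1\t28",
               "c1\t10\t+\t2\ts1\t28",
               "c1\t11\t-\t1\ts1\t29"), f)
  tr <- read_psites(f)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr[pos == 10L, count], 5L)
  # empty file is an empty track, not an error
  fe <- tempfile(); file.create(fe)
  expect_equal(nrow(read_psites(fe)), 0L)
  # negative counts and out-of-range positions are hard errors
  expect_error(psite_track(data.table::data.table(
    sample = "s", chrom = "c1", strand = "+", pos = 1L, count = -1L)),
    "negative")
  expect_error(psite_track(data.table::data.table(
    sample = "s", chrom = "c1", strand = "+", pos = 100L, count = 1L),
    chromosomes = c(c1 = 50L)), "beyond chromosome")
})
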