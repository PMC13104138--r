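STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Configuration for the synthetic translatome generator
#'
#' Defaults emulate the study design the pipeline targets: ten staged
#' samples (anther lengths 0.5-5.0 mm plus mature pollen) in five phases,
#' two replicates, footprints of 25-33 nt, frame-biased P-sites on
#' translated ORFs (default frame probabilities 0.75/0.15/0.10) and
#' uniform frames elsewhere, gene-specific translation efficiency, and
#' planted AUG-initiated ORFs in 5' UTRs, 3' UTRs and noncoding
#' transcripts with controlled Kozak context and a translated/untranslated
#' split.
#'
#' @param seed integer seed; all randomness in the generator derives from
#'   it (sub-steps use `seed`, `seed + 1`, `seed + 2`).
#' @param n_genes number of protein-coding genes.
#' @param n_nc_transcripts number of intergenic noncoding transcripts.
#' @param n_stages,n_replicates study layout (>= 2 stages).
#' @param stage_names,phase_map stage labels and stage -> phase assignment;
#'   defaults: `S01..S10` with stages 1-3 phase PI, 4-7 PII, 8 PIII,
#'   9 PIV, 10 PV.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   per-gene baseline mRNA abundance (arbitrary density units).
#' @param stage_effect_sdlog log-sd of the per-gene per-stage abundance
#'   multiplier.
#' @param te_meanlog,te_sdlog log-normal parameters of gene translation
#'   efficiency.
#' @param frame_probs P-site frame probabilities (frame 0/1/2) within
#'   codons of translated ORFs; untranslated positions are uniform.
#' @param length_probs named numeric over footprint lengths 25..33 nt.
#' @param init_peak_weight relative multinomial weight of the start codon
#'   in translated regions (initiation peak of the metagene profile).
#' @param rna_depth,ribo_depth expected fragments (RNA) / footprints
#'   (Ribo) per abundance unit per kilobase per library.
#' @param background_rate non-ORF footprint density on transcripts, as a
#'   fraction of the mean coding density.
#' @param utr5_range,utr3_range,cds_codons_range,nc_len_range,
#'   intergenic_gap structural length ranges (nt; CDS in codons).
#' @param two_exon_fraction,minus_fraction fraction of genes with one
#'   intron / on the minus strand.
#' @param n_chromosomes chromosomes the units are distributed over.
#' @param orf_plan list: `n_five`, `n_three`, `n_nc` planted ORF counts,
#'   `codons_range`, `strong_kozak_fraction`, `translated_fraction`,
#'   `level_meanlog`/`level_sdlog` (translation level of translated
#'   planted ORFs), `level_stage_sdlog` (per-stage jitter), and
#'   `length_te_slope` (host-gene log-TE shift per SD of 3' ORF length;
#'   0 = no planted length effect).
#' @param n_archetype_genes_per_phase when > 0, that many genes per phase
#'   get a phase-specific TE archetype (`archetype_te["high"]` within the
#'   phase, `archetype_te["low"]` elsewhere) for cluster-recovery studies.
#' @param archetype_te named numeric `c(low=, high=)`.
#' @param psite_mode `"psite"` emits P-sites directly; `"raw"` emits
#'   5'-end read placements offset upstream by `psite_offset`.
#' @param psite_offset true 5'-end to P-site offset (nt) in raw mode.
#' @param nb_dispersion optional negative-binomial size parameter for
#'   counts; `NULL` keeps pure Poisson.
#' @param isoform_backed_fraction fraction of translated 3' ORFs for which
#'   a matching independent isoform model is emitted.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L,
                       n_nc_transcripts = 80L,
                       n_stages = 10L,
                       n_replicates = 2L,
                       stage_names = NULL,
                       phase_map = NULL,
                       abundance_meanlog = log(20),
                       abundance_sdlog = 1,
                       stage_effect_sdlog = 0.5,
                       te_meanlog = 0,
                       te_sdlog = 0.5,
                       frame_probs = c(0.75, 0.15, 0.10),
                       length_probs = c(`25` = 0.02, `26` = 0.04,
                                        `27` = 0.10, `28` = 0.30,
                                        `29` = 0.24, `30` = 0.14,
                                        `31` = 0.08, `32` = 0.05,
                                        `33` = 0.03),
                       init_peak_weight = 8,
                       rna_depth = 20,
                       ribo_depth = 10,
                       background_rate = 0.02,
                       utr5_range = c(180L, 300L),
                       utr3_range = c(180L, 300L),
                       cds_codons_range = c(100L, 300L),
                       nc_len_range = c(400L, 800L),
                       intergenic_gap = c(200L, 400L),
                       two_exon_fraction = 0.3,
                       minus_fraction = 0.5,
                       n_chromosomes = 4L,
                       orf_plan = list(),
                       n_archetype_genes_per_phase = 0L,
                       archetype_te = c(low = 1.2, high = 6),
                       psite_mode = c("psite", "raw"),
                       psite_offset = 12L,
                       nb_dispersion = NULL,
                       isoform_backed_fraction = 0.5) {
  psite_mode <- match.arg(psite_mode)
  if (is.null(stage_names)) {
    stage_names <- sprintf("S%02d", seq_len(n_stages))
  }
  if (is.null(phase_map)) {
    phase_map <- if (n_stages == 10L) {
      c("PI", "PI", "PI", "PII", "PII", "PII", "PII", "PIII", "PIV", "PV")
    } else {
      rep("PI", n_stages)
    }
  }
  plan_default <- list(n_five = 170L, n_three = 170L, n_nc = 80L,
                      codons_range = c(10L, 45L),
                      strong_kozak_fraction = 0.5,
                      translated_fraction = 0.5,
                      level_meanlog = log(20), level_sdlog = 0.5,
                      level_stage_sdlog = 0.3,
                      length_te_slope = 0)
  orf_plan <- utils::modifyList(plan_default, orf_plan)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_nc_transcripts = as.integer(n_nc_transcripts),
              n_stages = as.integer(n_stages),
              n_replicates = as.integer(n_replicates),
              stage_names = stage_names, phase_map = phase_map,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              stage_effect_sdlog = stage_effect_sdlog,
              te_meanlog = te_meanlog, te_sdlog = te_sdlog,
              frame_probs = frame_probs, length_probs = length_probs,
              init_peak_weight = init_peak_weight,
              rna_depth = rna_depth, ribo_depth = ribo_depth,
              background_rate = background_rate,
              utr5_range = utr5_range, utr3_range = utr3_range,
              cds_codons_range = cds_codons_range,
              nc_len_range = nc_len_range,
              intergenic_gap = intergenic_gap,
              two_exon_fraction = two_exon_fraction,
              minus_fraction = minus_fraction,
              n_chromosomes = as.integer(n_chromosomes),
              orf_plan = orf_plan,
              n_archetype_genes_per_phase =
                as.integer(n_archetype_genes_per_phase),
              archetype_te = archetype_te,
              psite_mode = psite_mode,
              psite_offset = as.integer(psite_offset),
              nb_dispersion = nb_dispersion,
              isoform_backed_fraction = isoform_backed_fraction)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(abs(sum(cfg$frame_probs) - 1) < 1e-9,
              "frame_probs must sum to 1")
  assert_that(abs(sum(cfg$length_probs) - 1) < 1e-9,
              "length_probs must sum to 1")
  assert_that(cfg$n_stages >= 2L, "need at least 2 stages")
  assert_that(cfg$rna_depth > 0 && cfg$ribo_depth > 0, "depth must be > 0")
  assert_that(length(cfg$stage_names) == cfg$n_stages,
              "stage_names length mismatch")
  assert_that(length(cfg$phase_map) == cfg$n_stages,
              "phase_map length mismatch")
  assert_that(cfg$orf_plan$n_nc <= cfg$n_nc_transcripts,
              "more ncORFs requested than noncoding transcripts")
  assert_that(cfg$orf_plan$n_five <= cfg$n_genes &&
              cfg$orf_plan$n_three <= cfg$n_genes,
              "more UTR-ORFs requested than genes")
  invisible(cfg)
}

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_sense_codons <- function(n) {
  if (n == 0L) return("")
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

# Build an AUG..stop ORF sequence of `codons` total codons (start + interior
# + stop) whose +4 base (first base of codon 2) matches the requested Kozak
# strength.
build_orf_seq <- function(codons, strong) {
  stopifnot(codons >= 3L)
  second_pool <- if (strong) {
    grep("^G", SENSE_CODONS, value = TRUE)
  } else {
    grep("^[ACT]", SENSE_CODONS, value = TRUE)
  }
  paste0("ATG", sample(second_pool, 1L),
         random_sense_codons(codons - 3L),
         sample(STOP_CODONS, 1L))
}

# In a character vector `chars` (one base per element), remove any ATG
# upstream of and in frame with the AUG at `aug` (0-based index into the
# transcript) that is not separated from it by an in-frame stop; such an
# ATG would absorb the planted ORF under same-stop collapsing. Triplets
# overlapping `protect` (0-based half-open interval, e.g. the mORF start
# codon) are left untouched.
scrub_upstream_starts <- function(chars, aug, protect = NULL) {
  p <- aug - 3L
  while (p >= 0L) {
    tri <- paste(chars[(p + 1L):(p + 3L)], collapse = "")
    if (tri %in% STOP_CODONS) break
    if (tri == "ATG") {
      overlaps_protect <- !is.null(protect) &&
        p < protect[2] && (p + 3L) > protect[1]
      if (!overlaps_protect) chars[p + 3L] <- "C"  # ATG -> ATC
    }
    p <- p - 3L
  }
  chars
}

# Set the Kozak -3 base (A/G for strong, C/T for weak) without creating a
# new in-frame upstream ATG at the -3 triplet.
set_kozak_minus3 <- function(chars, aug, strong) {
  if (aug < 3L) return(chars)
  chars[aug - 2L] <- if (strong) sample(c("A", "G"), 1L) else
    sample(c("C", "T"), 1L)
  if (paste(chars[(aug - 2L):aug], collapse = "") == "ATG") {
    chars[aug - 1L] <- "C"
  }
  chars
}

# Plant an ORF of `codons` codons inside region [region_start, region_end)
# of the transcript character vector; returns list(chars, t_start, t_end).
plant_orf <- function(chars, region_start, region_end, codons, strong,
                      protect = NULL) {
  len <- 3L * codons
  lo <- region_start + 6L
  hi <- region_end - len
  assert_that(hi >= lo, "UTR too short for requested ORF length")
  o <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  orf <- strsplit(build_orf_seq(codons, strong), "")[[1]]
  chars[(o + 1L):(o + len)] <- orf
  chars <- scrub_upstream_starts(chars, o, protect = protect)
  chars <- set_kozak_minus3(chars, o, strong)
  list(chars = chars, t_start = o, t_end = o + len)
}

#' Generate a toy genome, annotation and ground truth
#'
#' Lays out protein-coding genes (5' UTR + CDS + 3' UTR, a configurable
#' fraction with one intron, mixed strands) and intergenic noncoding
#' transcripts over a small set of chromosomes, planting AUG-initiated
#' ORFs in UTRs and noncoding transcripts per the configured plan. Planted
#' ORFs begin with AUG, end at their first in-frame stop, carry the
#' requested Kozak context at -3/+4, and have any same-frame upstream AUG
#' (which would absorb them under same-stop collapsing) scrubbed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character), `annot`
#'   ([annotation_set()]), and `truth`: `genes` (gene x stage abundance
#'   and TE parameters), `orfs` (planted ORF table with transcript
#'   coordinates, category, Kozak and translated flags, levels), `stages`,
#'   and `features` (per-gene exon/CDS lengths).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  op <- config$orf_plan

  n_g <- config$n_genes
  n_nc <- config$n_nc_transcripts
  five_hosts <- sort(sample.int(n_g, op$n_five))
  three_hosts <- sort(sample.int(n_g, op$n_three))
  nc_hosts <- sort(sample.int(n_nc, op$n_nc))

  orf_rows <- list()
  units <- vector("list", n_g + n_nc)

  draw_codons <- function() {
    sample(seq.int(op$codons_range[1], op$codons_range[2]), 1L)
  }

  for (i in seq_len(n_g)) {
    u5 <- sample(seq.int(config$utr5_range[1], config$utr5_range[2]), 1L)
    u3 <- sample(seq.int(config$utr3_range[1], config$utr3_range[2]), 1L)
    ncod <- sample(seq.int(config$cds_codons_range[1],
                           config$cds_codons_range[2]), 1L)
    cds_len <- 3L * ncod
    cds_seq <- paste0("ATG", random_sense_codons(ncod - 2L),
                      sample(STOP_CODONS, 1L))
    chars <- strsplit(paste0(random_dna(u5), cds_seq, random_dna(u3)),
                      "")[[1]]
    tx_len <- u5 + cds_len + u3
    protect <- c(u5, u5 + 3L)  # mORF start codon
    gid <- sprintf("gene%04d", i)
    tid <- sprintf("tx%04d", i)
    for (cat in c("five_prime_ORF", "three_prime_ORF")) {
      hosts <- if (cat == "five_prime_ORF") five_hosts else three_hosts
      if (!(i %in% hosts)) next
      codons <- draw_codons()
      strong <- runif(1) < op$strong_kozak_fraction
      reg <- if (cat == "five_prime_ORF") c(0L, u5) else
        c(u5 + cds_len, tx_len)
      res <- plant_orf(chars, reg[1], reg[2], codons, strong,
                       protect = protect)
      chars <- res$chars
      orf_rows[[length(orf_rows) + 1L]] <- data.table::data.table(
        tx_id = tid, gene_id = gid, category = cat,
        t_start = res$t_start, t_end = res$t_end, codons = codons,
        kozak_strong = strong)
    }
    units[[i]] <- list(kind = "gene", gene_id = gid, tx_id = tid,
                       chars = chars, u5 = u5, cds_len = cds_len,
                       tx_len = tx_len)
  }

  for (j in seq_len(n_nc)) {
    len <- sample(seq.int(config$nc_len_range[1], config$nc_len_range[2]),
                  1L)
    chars <- strsplit(random_dna(len), "")[[1]]
    gid <- sprintf("ncgene%04d", j)
    tid <- sprintf("nctx%04d", j)
    if (j %in% nc_hosts) {
      codons <- draw_codons()
      strong <- runif(1) < op$strong_kozak_fraction
      res <- plant_orf(chars, 0L, len, codons, strong)
      chars <- res$chars
      orf_rows[[length(orf_rows) + 1L]] <- data.table::data.table(
        tx_id = tid, gene_id = gid, category = "ncORF",
        t_start = res$t_start, t_end = res$t_end, codons = codons,
        kozak_strong = strong)
    }
    units[[n_g + j]] <- list(kind = "nc", gene_id = gid, tx_id = tid,
                             chars = chars, u5 = NA_integer_,
                             cds_len = 0L, tx_len = len)
  }

  # genome layout: shuffled units round-robin over chromosomes
  ord <- sample(length(units))
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_seq <- stats::setNames(rep(list(character()), length(chrom_names)),
                               chrom_names)
  cursor <- stats::setNames(rep(0L, length(chrom_names)), chrom_names)

  gene_rows <- list(); tx_rows <- list(); exon_rows <- list()
  cds_rows <- list()
  for (k in seq_along(ord)) {
    u <- units[[ord[k]]]
    chrom <- chrom_names[(k - 1L) %% length(chrom_names) + 1L]
    strand <- if (runif(1) < config$minus_fraction) "-" else "+"
    tx_len <- u$tx_len
    two_exon <- u$kind == "gene" && runif(1) < config$two_exon_fraction
    if (two_exon) {
      sp <- sample(seq.int(50L, tx_len - 50L), 1L)
      ilen <- sample(seq.int(60L, 150L), 1L)
      region <- paste0(paste(u$chars[1:sp], collapse = ""),
                       random_dna(ilen),
                       paste(u$chars[(sp + 1L):tx_len], collapse = ""))
      ex_t <- list(c(0L, sp), c(sp + ilen, tx_len + ilen))  # tx order
    } else {
      region <- paste(u$chars, collapse = "")
      ex_t <- list(c(0L, tx_len))
    }
    lr <- nchar(region)
    if (strand == "-") {
      region <- revcomp(region)
      ex_g <- lapply(ex_t, function(e) c(lr - e[2], lr - e[1]))
    } else {
      ex_g <- ex_t
    }
    gap <- sample(seq.int(config$intergenic_gap[1],
                          config$intergenic_gap[2]), 1L)
    at <- cursor[[chrom]] + gap
    chrom_seq[[chrom]] <- c(chrom_seq[[chrom]], random_dna(gap), region)
    cursor[[chrom]] <- at + lr
    g_start <- at; g_end <- at + lr
    gene_rows[[k]] <- data.table::data.table(
      gene_id = u$gene_id, chrom = chrom, strand = strand,
      start = g_start, end = g_end)
    tx_rows[[k]] <- data.table::data.table(
      tx_id = u$tx_id, gene_id = u$gene_id,
      biotype = if (u$kind == "gene") "protein_coding" else "noncoding")
    exon_rows[[k]] <- data.table::rbindlist(lapply(ex_g, function(e) {
      data.table::data.table(tx_id = u$tx_id, start = at + e[1],
                             end = at + e[2])
    }))
    if (u$kind == "gene") {
      # CDS occupies transcript positions [u5, u5 + cds_len); convert to
      # genome intervals through the (possibly split) exon layout
      cds_t <- c(u$u5, u$u5 + u$cds_len)
      pieces <- list()
      for (e_i in seq_along(ex_t)) {
        et <- ex_t[[e_i]]
        toff <- if (e_i == 1L) 0L else ex_t[[1]][2] - ex_t[[1]][1]
        lo <- max(cds_t[1], toff); hi <- min(cds_t[2], toff +
                                             (et[2] - et[1]))
        if (hi <= lo) next
        # within-exon offsets in tx orientation
        a <- et[1] + (lo - toff); b <- et[1] + (hi - toff)
        gi <- if (strand == "-") c(lr - b, lr - a) else c(a, b)
        pieces[[length(pieces) + 1L]] <- data.table::data.table(
          tx_id = u$tx_id, start = at + gi[1], end = at + gi[2])
      }
      cds_rows[[k]] <- data.table::rbindlist(pieces)
    }
  }
  genome <- vapply(chrom_seq, paste, character(1), collapse = "")
  chromosomes <- stats::setNames(nchar(genome), names(genome))
  annot <- annotation_set(
    chromosomes = chromosomes,
    genes = data.table::rbindlist(gene_rows),
    transcripts = data.table::rbindlist(tx_rows),
    exons = data.table::rbindlist(exon_rows),
    cds = data.table::rbindlist(cds_rows),
    provenance = list(source = "riboutr simulation", seed = config$seed))

  orfs <- if (length(orf_rows)) data.table::rbindlist(orf_rows) else
    data.table::data.table(tx_id = character(), gene_id = character(),
                           category = character(), t_start = integer(),
                           t_end = integer(), codons = integer(),
                           kozak_strong = logical())
  if (nrow(orfs) > 0L) {
    orfs[, orf_id := sprintf("porf%04d", seq_len(.N))]
    # exact split so planted translated/untranslated counts are by design
    orfs[, translated := {
      tr <- rep(FALSE, .N)
      tr[sample.int(.N, round(op$translated_fraction * .N))] <- TRUE
      tr
    }, by = category]
    orfs[, stop_tpos := t_end - 3L]
    orfs[, level := ifelse(translated,
                           rlnorm(.N, op$level_meanlog, op$level_sdlog), 0)]
    orfs[, isoform_backed := translated & category == "three_prime_ORF" &
           runif(.N) < config$isoform_backed_fraction]
  }

  # per-gene x stage abundance and TE parameters
  stages <- data.table::data.table(stage = config$stage_names,
                                   stage_idx = seq_len(config$n_stages),
                                   phase = config$phase_map)
  gene_ids <- sprintf("gene%04d", seq_len(n_g))
  base_ab <- rlnorm(n_g, config$abundance_meanlog, config$abundance_sdlog)
  te_g <- rlnorm(n_g, config$te_meanlog, config$te_sdlog)
  if (op$length_te_slope != 0 && nrow(orfs) > 0L) {
    o3 <- orfs[category == "three_prime_ORF"]
    if (nrow(o3) > 1L) {
      z <- (o3$codons - mean(o3$codons)) / sd(o3$codons)
      idx <- match(o3$gene_id, gene_ids)
      te_g[idx] <- te_g[idx] * exp(op$length_te_slope * z)
    }
  }
  tg <- data.table::CJ(gene_id = gene_ids, stage_idx = stages$stage_idx)
  tg[, abundance := base_ab[match(gene_id, gene_ids)] *
       rlnorm(.N, 0, config$stage_effect_sdlog)]
  tg[, te_param := te_g[match(gene_id, gene_ids)]]
  napp <- config$n_archetype_genes_per_phase
  if (napp > 0L) {
    phases <- unique(stages$phase)
    arch <- rep(phases, each = napp)[seq_len(min(napp * length(phases),
                                                 n_g))]
    arch_map <- stats::setNames(arch, gene_ids[seq_along(arch)])
    tg[, phase := stages$phase[stage_idx]]
    tg[gene_id %in% names(arch_map),
       te_param := ifelse(phase == arch_map[gene_id],
                          config$archetype_te[["high"]],
                          config$archetype_te[["low"]])]
    tg[, phase := NULL]
  }
  tg <- stages[, .(stage, stage_idx)][tg, on = "stage_idx"]

  features <- annot$transcripts[biotype == "protein_coding",
                                .(tx_id, gene_id, cds_len)]
  exon_len <- annot$exons[, .(exon_len = sum(width)), by = tx_id]
  features <- exon_len[features, on = "tx_id"]
  features[, `:=`(exon_kb = exon_len / 1000, cds_kb = cds_len / 1000)]

  truth <- list(genes = tg, orfs = orfs, stages = stages,
                features = features,
                archetype = if (napp > 0L)
                  data.table::data.table(gene_id = names(arch_map),
                                         phase = unname(arch_map))
                else NULL)
  list(genome = genome, annot = annot, truth = truth)
}

sample_counts <- function(n, mu, nb_size = NULL) {
  if (is.null(nb_size)) rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = nb_size)
}

#' Simulate staged RNA-seq fragment counts
#'
#' Gene-level fragment counts per stage and replicate, drawn
#' `Poisson(abundance x exon_kb x rna_depth)` independently across
#' replicates (negative binomial when `nb_dispersion` is set).
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [generate_genome()].
#' @return list with `counts` (data.table `gene_id`, `stage`, `rep`,
#'   `count`) and `lib_sizes` (total counted fragments per library).
#' @export
simulate_rna <- function(config, truth) {
  set.seed(config$seed + 1L)
  tg <- merge(truth$genes, truth$features[, .(gene_id, exon_kb)],
              by = "gene_id")
  out <- data.table::CJ(rep = seq_len(config$n_replicates),
                        key_id = seq_len(nrow(tg)))
  out <- cbind(out, tg[out$key_id, .(gene_id, stage, abundance, exon_kb)])
  out[, count := sample_counts(.N, abundance * exon_kb * config$rna_depth,
                               config$nb_dispersion)]
  counts <- out[, .(gene_id, stage, rep, count)]
  data.table::setorder(counts, stage, rep, gene_id)
  libs <- counts[, .(total = sum(count)), by = .(stage, rep)]
  list(counts = counts, lib_sizes = libs)
}

# Expected Ribo-seq P-site rates per translated unit (mORFs + planted
# translated ORFs) and background, per stage. Used both for sampling and
# for the noiseless TE estimand recorded in the truth table.
ribo_unit_rates <- function(config, truth) {
  tg <- merge(truth$genes, truth$features, by = "gene_id")
  morf <- tg[, .(unit_id = paste0("m_", gene_id), tx_id, gene_id, stage,
                 kind = "mORF",
                 rate = te_param * abundance * cds_kb * config$ribo_depth)]
  orf <- NULL
  if (nrow(truth$orfs) > 0L) {
    o <- truth$orfs[translated == TRUE]
    if (nrow(o) > 0L) {
      orf <- data.table::CJ(orf_id = o$orf_id, stage = config$stage_names,
                            sorted = FALSE)
      orf <- merge(orf, o[, .(orf_id, tx_id, gene_id, t_start, t_end,
                              level)], by = "orf_id")
      orf[, rate := level * (t_end - t_start) / 1000 * config$ribo_depth]
      orf <- orf[, .(unit_id = paste0("o_", orf_id), tx_id, gene_id,
                     stage, kind = "planted_orf", rate,
                     t_start, t_end)]
    }
  }
  list(morf = morf, orf = orf)
}

#' Simulate staged Ribo-seq P-site tracks
#'
#' For each library, P-site totals per translated unit (annotated mORFs
#' and planted translated ORFs) are Poisson in
#' `level x kb x ribo_depth`; positions are multinomial over codons
#' (with an initiation-peak weight on the start codon) and frames within
#' codons follow `frame_probs` relative to each unit's own start codon.
#' A uniform-frame background covers all transcript positions. Footprint
#' lengths are drawn from the configured 25-33 nt distribution. In
#' `psite_mode = "raw"` the returned `placements` hold 5' read ends
#' offset upstream of the true P-sites by `psite_offset`.
#'
#' @inheritParams simulate_rna
#' @param annot the [annotation_set()] from [generate_genome()].
#' @return list with `track` (P-site track, all libraries; `sample` is
#'   `"<stage>_r<rep>"`), `placements` (raw-mode 5'-end track or `NULL`)
#'   and `lib_sizes`.
#' @export
simulate_ribo <- function(config, truth, annot) {
  set.seed(config$seed + 2L)
  rates <- ribo_unit_rates(config, truth)
  tx <- annot$transcripts
  map <- tx_map(annot)
  data.table::setkey(map, tx_id, tpos)

  # unit table: one row per translated unit x stage, with transcript span
  units <- rbind(
    merge(rates$morf, tx[, .(tx_id, cds_tstart, cds_tend)],
          by = "tx_id")[, .(unit_id, tx_id, stage, rate,
                            t_start = cds_tstart, t_end = cds_tend)],
    if (!is.null(rates$orf))
      rates$orf[, .(unit_id, tx_id, stage, rate, t_start, t_end)]
  )
  if (!is.null(rates$orf)) {
    # per-stage jitter on planted ORF levels
    j <- rlnorm(nrow(units), 0, config$orf_plan$level_stage_sdlog)
    is_orf <- grepl("^o_", units$unit_id)
    units[is_orf, rate := rate * j[is_orf]]
  }

  mean_density <- truth$genes[, mean(te_param * abundance)]
  bg <- data.table::CJ(tx_id = tx$tx_id, stage = config$stage_names,
                       sorted = FALSE)
  bg <- merge(bg, tx[, .(tx_id, tx_len)], by = "tx_id")
  bg[, rate := config$background_rate * mean_density * tx_len / 1000 *
       config$ribo_depth]

  lens <- as.integer(names(config$length_probs))
  fp <- config$frame_probs
  pieces <- list()
  for (r in seq_len(config$n_replicates)) {
    # translated units: counts per codon x frame
    n_u <- sample_counts(nrow(units), units$rate, config$nb_dispersion)
    keep <- which(n_u > 0L)
    for (i in keep) {
      ncod <- (units$t_end[i] - units$t_start[i]) %/% 3L
      w <- rep(1, ncod); w[1] <- config$init_peak_weight
      codon_n <- as.vector(rmultinom(1L, n_u[i], w))
      nz <- which(codon_n > 0L)
      fr <- sample.int(3L, sum(codon_n), replace = TRUE, prob = fp) - 1L
      tp <- units$t_start[i] + 3L * (rep(nz - 1L, codon_n[nz])) + fr
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        tx_id = units$tx_id[i], stage = units$stage[i], rep = r, tpos = tp)
    }
    # background: uniform positions
    n_b <- sample_counts(nrow(bg), bg$rate, config$nb_dispersion)
    keepb <- which(n_b > 0L)
    if (length(keepb)) {
      idx <- rep(keepb, n_b[keepb])
      tp <- as.integer(floor(runif(length(idx)) * bg$tx_len[idx]))
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        tx_id = bg$tx_id[idx], stage = bg$stage[idx], rep = r, tpos = tp)
    }
  }
  reads <- data.table::rbindlist(pieces)
  if (nrow(reads) == 0L) {
    return(list(track = empty_psite_track(), placements = NULL,
                lib_sizes = data.table::data.table()))
  }
  reads[, read_length := sample(lens, .N, replace = TRUE,
                                prob = config$length_probs)]
  reads <- map[reads, on = .(tx_id, tpos)]
  reads[, sample := paste0(stage, "_r", rep)]
  track <- psite_track(reads[, .(sample, chrom, strand, pos = gpos,
                                 read_length, count = 1L)],
                       chromosomes = NULL)
  placements <- NULL
  if (config$psite_mode == "raw") {
    off <- config$psite_offset
    placements <- data.table::copy(track)
    placements[, pos := ifelse(strand == "+", pos - off, pos + off)]
    placements <- psite_track(placements)
  }
  libs <- track[, .(total = sum(count)), by = sample]
  list(track = track, placements = placements, lib_sizes = libs)
}

# Noiseless value of the TE estimand per gene x stage: expected RPKM over
# expected FPKM, using expected library totals (pseudocounts omitted; at
# the default scale they are negligible).
true_te_estimand <- function(config, truth) {
  rates <- ribo_unit_rates(config, truth)
  tg <- merge(truth$genes, truth$features, by = "gene_id")
  rna_tot <- tg[, .(rna_total = sum(abundance * exon_kb *
                                    config$rna_depth)), by = stage]
  morf <- rates$morf[, .(gene_id, stage, morf_rate = rate)]
  ribo_tot <- rates$morf[, .(t = sum(rate)), by = stage]
  if (!is.null(rates$orf)) {
    ot <- rates$orf[, .(t = sum(rate)), by = stage]
    ribo_tot <- rbind(ribo_tot, ot)[, .(t = sum(t)), by = stage]
  }
  mean_density <- truth$genes[, mean(te_param * abundance)]
  tx_kb_total <- sum(truth$features$exon_len) / 1000  # coding tx only
  # background covers all transcripts; recompute exactly
  bg_total <- config$background_rate * mean_density *
    (sum(truth$features$exon_len) / 1000) * config$ribo_depth
  ribo_tot[, t := t + bg_total]
  out <- merge(merge(tg, morf, by = c("gene_id", "stage")),
               merge(rna_tot, ribo_tot, by = "stage"), by = "stage")
  out[, e_fpkm := (abundance * exon_kb * config$rna_depth) / exon_kb /
        (rna_total / 1e6)]
  out[, e_rpkm := morf_rate / cds_kb / (t / 1e6)]
  out[, te_true := e_rpkm / e_fpkm]
  out[, .(gene_id, stage, te_true)]
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: genome + annotation + truth, RNA fragment counts,
#' Ribo-seq P-site tracks (and raw placements when configured), matching
#' isoform models for a subset of translated 3' ORFs, and a peptide list
#' (true sub-peptides of translated planted ORFs plus reversed decoys).
#' Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `genome`, `annot`, `truth` (gaining
#'   `te_true`, the noiseless TE estimand, in `truth$genes`), `rna`,
#'   `ribo`, `isoforms` (an [annotation_set()] or `NULL`) and `peptides`.
#' @export
simulate_dataset <- function(config) {
  gg <- generate_genome(config)
  truth <- gg$truth
  tt <- true_te_estimand(config, truth)
  truth$genes <- merge(truth$genes, tt, by = c("gene_id", "stage"),
                       all.x = TRUE)
  rna <- simulate_rna(config, truth)
  ribo <- simulate_ribo(config, truth, gg$annot)

  iso <- NULL
  if (nrow(truth$orfs) > 0L && any(truth$orfs$isoform_backed)) {
    iso <- build_isoforms(gg$annot, truth$orfs[isoform_backed == TRUE])
  }
  peptides <- build_peptides(gg$annot, gg$genome, truth$orfs,
                             seed = config$seed + 3L)
  list(config = config, genome = gg$genome, annot = gg$annot,
       truth = truth, rna = rna, ribo = ribo, isoforms = iso,
       peptides = peptides)
}

# Emit one single-gene isoform model per backed ORF: exons covering the
# ORF's transcript span plus 30 nt flanks, following the host exon chain.
build_isoforms <- function(annot, orfs) {
  gene_rows <- list(); tx_rows <- list(); exon_rows <- list()
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i]
    txr <- annot$transcripts[tx_id == o$tx_id]
    lo <- max(0L, o$t_start - 30L)
    hi <- min(txr$tx_len, o$t_end + 30L)
    blocks <- tpos_blocks(annot, o$tx_id, lo, hi)
    gid <- paste0("isog_", o$orf_id)
    tid <- paste0("isot_", o$orf_id)
    gene_rows[[i]] <- data.table::data.table(
      gene_id = gid, chrom = txr$chrom, strand = txr$strand,
      start = min(blocks$start), end = max(blocks$end))
    tx_rows[[i]] <- data.table::data.table(tx_id = tid, gene_id = gid,
                                           biotype = "noncoding")
    exon_rows[[i]] <- data.table::data.table(tx_id = tid,
                                             start = blocks$start,
                                             end = blocks$end)
  }
  annotation_set(chromosomes = annot$chromosomes,
                 genes = data.table::rbindlist(gene_rows),
                 transcripts = data.table::rbindlist(tx_rows),
                 exons = data.table::rbindlist(exon_rows),
                 provenance = list(source = "riboutr simulated isoforms"))
}

# Genome-interval blocks (0-based half-open, genome order) covered by
# transcript positions [t0, t1) of one transcript.
tpos_blocks <- function(annot, transcript_id, t0, t1) {
  m <- tx_map(annot, transcript_id)[tpos >= t0 & tpos < t1]
  data.table::setorder(m, gpos)
  runs <- cumsum(c(1L, diff(m$gpos) != 1L))
  m[, .(start = min(gpos), end = max(gpos) + 1L), by = .(run = runs)][
    , .(start, end)]
}

build_peptides <- function(annot, genome, orfs, seed, n_decoys = 25L,
                           frag_range = c(8L, 15L)) {
  set.seed(seed)
  res <- list()
  translated <- orfs[translated == TRUE]
  peps <- if (nrow(translated) > 0L) {
    dna <- vapply(seq_len(nrow(translated)), function(i) {
      ts <- spliced_sequence(annot, genome, translated$tx_id[i])
      substr(ts$seq, translated$t_start[i] + 1L, translated$t_end[i])
    }, character(1))
    translate_orf(dna)
  } else character()
  for (i in seq_len(nrow(translated))) {
    pep <- peps[i]
    if (nchar(pep) < frag_range[1] + 1L) next
    flen <- sample(seq.int(frag_range[1],
                           min(frag_range[2], nchar(pep))), 1L)
    at <- sample.int(nchar(pep) - flen + 1L, 1L)
    res[[length(res) + 1L]] <- data.table::data.table(
      peptide = substr(pep, at, at + flen - 1L),
      source_orf = translated$orf_id[i], decoy = FALSE)
  }
  pep_dt <- data.table::rbindlist(res)
  if (nrow(pep_dt) > 0L) {
    dec <- pep_dt[sample.int(.N, min(n_decoys, .N))]
    dec[, peptide := vapply(strsplit(peptide, ""),
                            function(x) paste(rev(x), collapse = ""),
                            character(1))]
    dec[, `:=`(decoy = TRUE, source_orf = NA_character_)]
    pep_dt <- rbind(pep_dt, dec)
  }
  pep_dt
}

#' Translate DNA ORFs (AUG..stop) to peptides
#'
#' Vectorized: one [Biostrings::translate()] call for the whole input.
#'
#' @param dna character vector of in-frame DNA strings whose final codon
#'   is the stop.
#' @return character vector of peptides without the stop.
#' @export
translate_orf <- function(dna) {
  if (length(dna) == 0L) return(character())
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(dna), if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genome.fa`, `annotation.gff3`, `rna_counts.tsv`,
#' `psites.tsv` (or `placements.tsv` in raw mode), `truth_genes.tsv`,
#' `truth_orfs.tsv`, `stages.tsv`, `config.yaml`, and, when present,
#' `isoforms.gff3` and `peptides.tsv`.
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_genome(sim$genome, p("genome.fa"))
  write_gff3(sim$annot, p("annotation.gff3"))
  data.table::fwrite(sim$rna$counts, p("rna_counts.tsv"), sep = "\t")
  write_psites(sim$ribo$track, p("psites.tsv"))
  if (!is.null(sim$ribo$placements)) {
    write_psites(sim$ribo$placements, p("placements.tsv"))
  }
  data.table::fwrite(sim$truth$genes, p("truth_genes.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$orfs, p("truth_orfs.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$stages, p("stages.tsv"), sep = "\t")
  yaml::write_yaml(unclass(sim$config), p("config.yaml"))
  if (!is.null(sim$isoforms)) write_gff3(sim$isoforms, p("isoforms.gff3"))
  if (!is.null(sim$peptides)) {
    data.table::fwrite(sim$peptides, p("peptides.tsv"), sep = "\t")
  }
  invisible(list.files(outdir, full.names = TRUE))
}

#' Paired matrices with a known translatome variance inflation
#'
#' Generates gene x stage transcriptome values
#' `log2 FPKM ~ N(meanlog2, sdlog2)` and translatome values whose
#' log-scale variance is inflated by a known fraction via independent
#' additive TE noise: `log2 RPKM = log2 FPKM + e`,
#' `e ~ N(0, inflation x sdlog2^2)`. Used to check that the
#' expression-variation statistic recovers a known inflation.
#'
#' @param n_genes,n_stages matrix dimensions.
#' @param inflation target fractional variance increase (0.3 = 30%).
#' @param meanlog2,sdlog2 location/scale of log2 expression.
#' @return list of matrices `rna` and `ribo` (linear scale), genes in
#'   rows, stages in columns.
#' @export
simulate_variation_matrices <- function(n_genes = 2000L, n_stages = 10L,
                                        inflation = 0.3, meanlog2 = 8,
                                        sdlog2 = 2) {
  base <- matrix(rnorm(n_genes * n_stages, meanlog2, sdlog2),
                 nrow = n_genes)
  e <- matrix(rnorm(n_genes * n_stages, 0, sqrt(inflation) * sdlog2),
              nrow = n_genes)
  dimnames(base) <- list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("S%02d", seq_len(n_stages)))
  ribo <- base + e
  dimnames(ribo) <- dimnames(base)
  list(rna = 2^base, ribo = 2^ribo)
}
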