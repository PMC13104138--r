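pipeline_param_defaults <- list(
  expressed_min = 1,      # FPKM/RPKM cutoff for expressed/translated calls
  min_psites = 10L,       # minimum P-sites for the periodicity test
  f0_min = 0.6,           # frame-0 fraction gate
  alpha = 0.05,           # periodicity test level
  expr_min = 50,          # expression gate for TE classification
  te_high = 2,            # high-TE threshold
  te_very_high = 5,       # very-high phase-mean TE threshold
  te_low = 0.5,           # low-TE threshold
  var_min_median = 1,     # median filter for expression variation
  profile_min = 1,        # minimum-TE filter before clustering
  k = 18L,                # k-means clusters
  kmeans_iter = 30L,      # k-means iteration cap
  kmeans_seed = 19960912, # k-means seed
  phase_margin = 0.2,     # phase-specificity margin
  peptide_min_len = 7L,   # peptide match minimum length
  n_terms = 12L           # synthetic annotation terms for enrichment
)

resolve_pipeline_config <- function(config) {
  if (inherits(config, "sim_config")) {
    return(list(simulate = config, params = list()))
  }
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list, sim_config or path")
  bad <- setdiff(names(config), c("simulate", "inputs", "params"))
  assert_that(length(bad) == 0L,
              paste("unknown config section(s):",
                    paste(bad, collapse = ", ")))
  if (!is.null(config$simulate) && !inherits(config$simulate,
                                             "sim_config")) {
    known <- names(formals(sim_config))
    bad <- setdiff(names(config$simulate), known)
    assert_that(length(bad) == 0L,
                paste("unknown simulate key(s):",
                      paste(bad, collapse = ", ")))
    config$simulate <- do.call(sim_config, config$simulate)
  }
  if (!is.null(config$params)) {
    bad <- setdiff(names(config$params), names(pipeline_param_defaults))
    assert_that(length(bad) == 0L,
                paste("unknown params key(s):",
                      paste(bad, collapse = ", ")))
  }
  if (!is.null(config$inputs)) {
    bad <- setdiff(names(config$inputs),
                   c("gff3", "genome", "psites", "placements",
                     "rna_counts", "stages"))
    assert_that(length(bad) == 0L,
                paste("unknown inputs key(s):",
                      paste(bad, collapse = ", ")))
  }
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> ingest -> P-site QC -> quantify -> ORF calling
#' -> TE classification / expression variation / ORF-TE relations ->
#' clustering + enrichment -> corroboration over a single configuration,
#' writing all tables under `outdir` together with a JSON run manifest
#' (config snapshot, seeds, per-step outputs, wall-clock, md5 checksums).
#' Reruns with an identical config produce identical checksums for all
#' outputs.
#'
#' @param config a [sim_config()] (simulated inputs), a list with
#'   sections `simulate` / `inputs` / `params`, or the path to a YAML
#'   file with those sections. Unknown keys are a validation error.
#' @param outdir output directory.
#' @return the manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config, outdir) {
  t_all <- Sys.time()
  config <- resolve_pipeline_config(config)
  params <- utils::modifyList(pipeline_param_defaults,
                              config$params %||% list())
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  steps <- list()
  run_step <- function(name, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      stop("step ", name, ": ", conditionMessage(e), call. = FALSE)
    })
    steps[[name]] <<- list(
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0,
                                            units = "secs")), 3),
      outputs = out$files %||% character())
    out
  }

  sim <- NULL
  st_sim <- run_step("simulate", function() {
    if (is.null(config$simulate)) return(list(files = character()))
    sim <<- simulate_dataset(config$simulate)
    files <- write_simulation(sim, p("sim"))
    list(files = files)
  })

  env <- new.env()
  run_step("ingest", function() {
    if (!is.null(sim)) {
      env$annot <- read_gff3(p("sim/annotation.gff3"))
      env$genome <- read_genome(p("sim/genome.fa"))
      env$rna_counts <- data.table::fread(p("sim/rna_counts.tsv"))
      env$stages <- sim$config$stage_names
      env$phase_map <- stats::setNames(sim$config$phase_map,
                                       sim$config$stage_names)
      if (sim$config$psite_mode == "raw") {
        env$placements <- sim$ribo$placements
      } else {
        env$track <- read_psites(p("sim/psites.tsv"),
                                 chromosomes = env$annot$chromosomes)
      }
      env$peptides <- sim$peptides
      env$isoforms <- sim$isoforms
    } else {
      ins <- config$inputs %||% list()
      if (!is.null(ins$gff3)) env$annot <- read_gff3(ins$gff3)
      if (!is.null(ins$genome)) env$genome <- read_genome(ins$genome)
      if (!is.null(ins$rna_counts)) {
        env$rna_counts <- data.table::fread(ins$rna_counts)
      }
      if (!is.null(ins$psites)) env$track <- read_psites(ins$psites)
      if (!is.null(ins$placements)) {
        env$placements <- read_psites(ins$placements)
      }
      if (!is.null(ins$stages)) {
        st <- data.table::fread(ins$stages)
        env$stages <- st$stage
        env$phase_map <- stats::setNames(st$phase, st$stage)
      }
    }
    list(files = character())
  })

  run_step("psite_qc", function() {
    files <- character()
    if (!is.null(env$placements)) {
      ap <- assign_psites(env$placements, env$annot)
      env$track <- ap$track
      data.table::fwrite(ap$offsets, p("offsets.tsv"), sep = "\t")
      files <- c(files, p("offsets.tsv"))
    }
    if (!is.null(env$track)) {
      lh <- length_histogram(env$track)
      if (lh$available && !is.null(lh$hist)) {
        data.table::fwrite(lh$hist, p("length_hist.tsv"), sep = "\t")
        files <- c(files, p("length_hist.tsv"))
      }
      env$length_qc <- lh
    }
    list(files = files)
  })

  run_step("quantify", function() {
    assert_that(!is.null(env$track),
                "no P-site track available (provide psites/placements or a simulate section)")
    assert_that(!is.null(env$rna_counts), "no RNA counts available")
    env$expr <- quantify_expression(env$annot, env$rna_counts, env$track,
                                    env$stages)
    env$te <- compute_te(env$expr)
    env$calls <- call_expressed(env$expr, threshold = params$expressed_min)
    wmat <- function(m, f) {
      dt <- data.table::as.data.table(m, keep.rownames = "gene_id")
      data.table::fwrite(dt, p(f), sep = "\t")
      p(f)
    }
    files <- c(wmat(env$expr$rna, "fpkm.tsv"),
               wmat(env$expr$ribo, "rpkm.tsv"),
               wmat(env$te$te, "te.tsv"))
    data.table::fwrite(env$calls$summary, p("expressed_summary.tsv"),
                       sep = "\t")
    list(files = c(files, p("expressed_summary.tsv")))
  })

  run_step("callorfs", function() {
    env$orfs <- discover_orfs(env$annot, env$genome)
    env$acc <- accept_translated(env$orfs, env$track, env$annot,
                                 env$stages, min_n = params$min_psites,
                                 f0_min = params$f0_min,
                                 alpha = params$alpha)
    data.table::fwrite(env$acc$orfs, p("orfs.tsv"), sep = "\t")
    files <- p("orfs.tsv")
    if (!is.null(env$acc$stage_stats)) {
      data.table::fwrite(env$acc$stage_stats, p("orf_stage_stats.tsv"),
                         sep = "\t")
      files <- c(files, p("orf_stage_stats.tsv"))
    }
    accepted <- env$acc$orfs[accepted == TRUE]
    if (nrow(accepted) > 0L) {
      write_orfs_bed12(env$annot, accepted, p("orfs.bed12"))
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(stats::setNames(accepted$peptide,
                                                accepted$orf_id)),
        p("peptides.fa"))
      files <- c(files, p("orfs.bed12"), p("peptides.fa"))
    }
    list(files = files)
  })

  run_step("classify_te", function() {
    env$te_classes <- classify_te(env$expr, env$te,
                                  expr_min = params$expr_min,
                                  high = params$te_high,
                                  very_high = params$te_very_high,
                                  low = params$te_low,
                                  phase_map = env$phase_map)
    data.table::fwrite(env$te_classes$genes, p("te_classes.tsv"),
                       sep = "\t")
    ev <- expression_variation(env$expr$rna, env$expr$ribo,
                               min_median = params$var_min_median)
    env$variation <- ev
    data.table::fwrite(ev$report, p("variance_report.tsv"), sep = "\t")
    files <- c(p("te_classes.tsv"), p("variance_report.tsv"))
    accepted <- env$acc$orfs[accepted == TRUE]
    if (nrow(accepted) > 0L) {
      rel <- orf_te_relations(accepted, env$acc$orf_rpkm, env$te)
      env$orf_relations <- rel
      data.table::fwrite(rel$per_orf, p("orf_te_relations.tsv"),
                         sep = "\t")
      files <- c(files, p("orf_te_relations.tsv"))
    }
    list(files = files)
  })

  run_step("cluster_enrich", function() {
    m <- normalize_profiles(env$te, min_value = params$profile_min)
    files <- character()
    if (nrow(m) >= params$k) {
      cl <- kmeans_te(m, k = params$k, max_iter = params$kmeans_iter,
                      seed = params$kmeans_seed,
                      phase_map = env$phase_map,
                      margin = params$phase_margin)
      env$clusters <- cl
      data.table::fwrite(
        data.table::data.table(gene_id = names(cl$assignments),
                               cluster = cl$assignments),
        p("clusters.tsv"), sep = "\t")
      cent <- data.table::as.data.table(cl$centroids,
                                        keep.rownames = "cluster")
      data.table::fwrite(cent, p("centroids.tsv"), sep = "\t")
      files <- c(p("clusters.tsv"), p("centroids.tsv"))
      # synthetic opaque term annotation for the enrichment demo
      seed_terms <- (if (!is.null(sim)) sim$config$seed else 0L) + 10L
      set.seed(seed_terms)
      background <- rownames(env$te$te)
      terms <- data.table::rbindlist(lapply(
        seq_len(params$n_terms), function(i) {
          data.table::data.table(
            term = sprintf("TERM%03d", i),
            gene_id = sample(background,
                             max(5L, round(length(background) * 0.1))))
        }))
      sets <- split(names(cl$assignments), cl$assignments)
      names(sets) <- paste0("cluster", names(sets))
      enr <- hypergeom_enrich(sets, terms, background)
      env$enrichment <- enr
      data.table::fwrite(enr, p("enrichment.tsv"), sep = "\t")
      files <- c(files, p("enrichment.tsv"))
    }
    hs <- hclust_stages(log2(env$expr$rna + 1))
    writeLines(hs$newick, p("stage_dendrogram_rna.nwk"))
    hs2 <- hclust_stages(log2(env$expr$ribo + 1))
    writeLines(hs2$newick, p("stage_dendrogram_ribo.nwk"))
    list(files = c(files, p("stage_dendrogram_rna.nwk"),
                   p("stage_dendrogram_ribo.nwk")))
  })

  run_step("corroborate", function() {
    files <- character()
    accepted <- env$acc$orfs[accepted == TRUE]
    if (!is.null(env$peptides) && nrow(env$peptides) > 0L &&
        nrow(accepted) > 0L) {
      mp <- match_peptides(env$peptides,
                           stats::setNames(accepted$peptide,
                                           accepted$orf_id),
                           min_len = params$peptide_min_len)
      data.table::fwrite(mp$matches, p("peptide_matches.tsv"), sep = "\t")
      files <- c(files, p("peptide_matches.tsv"))
    }
    if (!is.null(env$isoforms) && nrow(accepted) > 0L) {
      iso <- isoform_support(accepted, env$annot, env$isoforms)
      data.table::fwrite(iso, p("isoform_support.tsv"), sep = "\t")
      files <- c(files, p("isoform_support.tsv"))
    }
    list(files = files)
  })

  all_outputs <- sort(setdiff(list.files(outdir, recursive = TRUE,
                                         full.names = TRUE),
                              p("manifest.json")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("riboutr")),
    config = if (!is.null(config$simulate)) unclass(config$simulate)
             else config$inputs,
    params = params,
    steps = steps,
    checksums = as.list(file_checksums(all_outputs)),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t_all,
                                          units = "secs")), 3))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write ORF calls as BED12
#'
#' @param annot an [annotation_set()].
#' @param orfs ORF table with `orf_id`, `tx_id`, `t_start`, `t_end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orfs_bed12 <- function(annot, orfs, path) {
  blocks <- orf_genome_blocks(annot, orfs)
  rows <- blocks[, {
    bs <- start - min(start)
    sz <- end - start
    .(chrom = chrom[1], chromStart = min(start), chromEnd = max(end),
      strand = strand[1], blockCount = .N,
      blockSizes = paste0(paste(sz, collapse = ","), ","),
      blockStarts = paste0(paste(bs, collapse = ","), ","))
  }, by = orf_id]
  bed <- rows[, .(chrom, chromStart, chromEnd, name = orf_id, score = 0L,
                  strand, thickStart = chromStart, thickEnd = chromEnd,
                  itemRgb = 0L, blockCount, blockSizes, blockStarts)]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
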