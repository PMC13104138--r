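#' TE-based gene classification
#'
#' A stage qualifies for a gene iff `max(FPKM, RPKM) >= expr_min` at that
#' stage. At qualifying stages, `TE > high` labels the stage `high` and
#' `TE < low` labels it `low`; other qualifying stages are `none` and
#' non-qualifying stages `unqualified`. Gene-level classes: `high` if
#' high at >= 1 stage; `very_high` if additionally the phase-mean TE
#' (arithmetic mean of the stage TEs within a phase) exceeds `very_high`
#' for >= 1 phase; `low` if low at >= 1 stage and never high;
#' `fluctuating` if both high and low occur; `none` otherwise. Genes
#' qualifying at no stage are `none` with `qualified = FALSE`.
#'
#' @param expr an `ExpressionMatrix`.
#' @param te a `TEProfile`.
#' @param expr_min expression gate (FPKM or RPKM; default 50).
#' @param high,very_high,low TE thresholds (defaults 2, 5, 0.5).
#' @param phase_map named character vector stage -> phase.
#' @return list with `genes` (data.table `gene_id`, `class`,
#'   `qualified`, `n_high_stages`, `n_low_stages`, `max_phase_te`) and
#'   `stage_labels` (gene x stage character matrix).
#' @export
classify_te <- function(expr, te, expr_min = 50, high = 2, very_high = 5,
                        low = 0.5, phase_map) {
  genes <- rownames(te$te)
  stages <- colnames(te$te)
  assert_that(all(stages %in% names(phase_map)),
              "phase_map must cover all stages")
  fpkm <- expr$rna[genes, stages, drop = FALSE]
  rpkm <- expr$ribo[genes, stages, drop = FALSE]
  qual <- pmax(fpkm, rpkm) >= expr_min
  labels <- matrix("unqualified", nrow = length(genes),
                   ncol = length(stages), dimnames = list(genes, stages))
  labels[qual] <- "none"
  labels[qual & te$te > high] <- "high"
  labels[qual & te$te < low] <- "low"

  phases <- unique(unname(phase_map[stages]))
  phase_means <- sapply(phases, function(p) {
    cols <- stages[phase_map[stages] == p]
    rowMeans(te$te[, cols, drop = FALSE])
  })
  if (is.null(dim(phase_means))) {
    phase_means <- matrix(phase_means, ncol = length(phases),
                          dimnames = list(genes, phases))
  }
  gl <- data.table::data.table(
    gene_id = genes,
    qualified = rowSums(qual) > 0L,
    n_high_stages = rowSums(labels == "high"),
    n_low_stages = rowSums(labels == "low"),
    max_phase_te = apply(phase_means, 1L, max))
  gl[, class := data.table::fcase(
    !qualified, "none",
    n_high_stages > 0L & n_low_stages > 0L, "fluctuating",
    n_high_stages > 0L & max_phase_te > very_high, "very_high",
    n_high_stages > 0L, "high",
    n_low_stages > 0L, "low",
    default = "none")]
  list(genes = gl[], stage_labels = labels)
}

population_var <- function(x) {
  m <- mean(x)
  sum((x - m)^2) / length(x)
}

#' Translatome vs transcriptome expression variation
#'
#' Retains genes whose median expression across stages exceeds
#' `min_median` in the respective layer (the two filters intersected so
#' both layers use the identical gene set), then reports the population
#' variance (1/n denominator) of expression across genes at each stage,
#' for both layers, on the `log2(x + 1)` scale (headline) and on the raw
#' scale, with the percent increase
#' `100 * (var_ribo - var_rna) / var_rna` per stage.
#'
#' @param rna,ribo gene x stage matrices (FPKM / RPKM); rownames are
#'   matched on the intersection.
#' @param min_median median filter threshold (exclusive; default 1).
#' @return list with `report` (per-stage data.table), `genes_used`, and
#'   `filter` (record of gene counts before/after filtering).
#' @export
expression_variation <- function(rna, ribo, min_median = 1) {
  genes <- intersect(rownames(rna), rownames(ribo))
  stages <- intersect(colnames(rna), colnames(ribo))
  rna <- rna[genes, stages, drop = FALSE]
  ribo <- ribo[genes, stages, drop = FALSE]
  keep <- apply(rna, 1L, median) > min_median &
    apply(ribo, 1L, median) > min_median
  assert_that(sum(keep) >= 2L,
              "fewer than 2 genes pass the median expression filter")
  rna <- rna[keep, , drop = FALSE]
  ribo <- ribo[keep, , drop = FALSE]
  lrna <- log2(rna + 1); lribo <- log2(ribo + 1)
  report <- data.table::rbindlist(lapply(stages, function(s) {
    v_rna <- population_var(lrna[, s]); v_ribo <- population_var(lribo[, s])
    vr_rna <- population_var(rna[, s]); vr_ribo <- population_var(ribo[, s])
    data.table::data.table(
      stage = s,
      var_rna_log2 = v_rna, var_ribo_log2 = v_ribo,
      pct_increase_log2 = 100 * (v_ribo - v_rna) / v_rna,
      var_rna_raw = vr_rna, var_ribo_raw = vr_ribo,
      pct_increase_raw = 100 * (vr_ribo - vr_rna) / vr_rna)
  }))
  list(report = report, genes_used = rownames(rna),
       filter = list(n_total = length(genes), n_used = sum(keep),
                     min_median = min_median))
}

# Tukey HSD letters for a one-way layout; returns list(anova_p, groups dt)
tukey_groups <- function(value, group, alpha = 0.05) {
  dt <- data.table::data.table(value = value, group = factor(group))
  dt <- dt[!is.na(value)]
  lev <- levels(droplevels(dt$group))
  if (length(lev) < 2L || dt[, .N, by = group][, min(N)] < 2L) {
    return(list(anova_p = NA_real_,
                groups = dt[, .(n = .N, mean = mean(value)), by = group][
                  , letters := "a"][]))
  }
  fit <- aov(value ~ group, data = dt)
  an_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$group
  sig <- matrix(FALSE, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (nm in rownames(tk)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    s <- tk[nm, "p adj"] < alpha
    sig[pair[1], pair[2]] <- s
    sig[pair[2], pair[1]] <- s
  }
  let <- cld_letters(sig)
  g <- dt[, .(n = .N, mean = mean(value)), by = group]
  g[, letters := let[as.character(group)]]
  list(anova_p = an_p, groups = g[])
}

#' Relationships between UTR-ORF features and host-gene TE
#'
#' Reports (a) per accepted ORF, the Pearson correlation between its
#' per-stage translation level and the host gene's per-stage TE
#' (undefined with fewer than 3 informative stages or zero variance);
#' (b) host-gene TE (mean over stages) grouped by the number of ORFs of
#' each class (0 / 1 / 2+) and by strong-Kozak presence, compared by
#' one-way ANOVA with Tukey HSD letters; (c) the Spearman rank
#' correlation between ORF length and host-gene TE per class.
#'
#' @param orfs accepted ORF table (with `orf_id`, `gene_id`, `category`,
#'   `t_start`, `t_end`, `kozak_strong`).
#' @param orf_rpkm per ORF x stage translation levels
#'   (from [accept_translated()]).
#' @param te a `TEProfile`.
#' @return list `per_orf`, `count_groups`, `kozak_groups`,
#'   `length_correlation`.
#' @export
orf_te_relations <- function(orfs, orf_rpkm, te) {
  te_mat <- te$te
  stages <- colnames(te_mat)
  gene_mean_te <- rowMeans(te_mat)

  per_orf <- data.table::rbindlist(lapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i]
    r <- NA_real_; p <- NA_real_
    if (!is.na(o$gene_id) && o$gene_id %in% rownames(te_mat)) {
      lev <- orf_rpkm[orf_id == o$orf_id][match(stages, stage), value]
      gte <- te_mat[o$gene_id, ]
      ok <- complete.cases(lev, gte)
      if (sum(ok) >= 3L && sd(lev[ok]) > 0 && sd(gte[ok]) > 0) {
        ct <- suppressWarnings(cor.test(lev[ok], gte[ok],
                                        method = "pearson"))
        r <- unname(ct$estimate); p <- ct$p.value
      }
    }
    data.table::data.table(orf_id = o$orf_id, gene_id = o$gene_id,
                           category = o$category, pearson_r = r,
                           p_value = p)
  }))

  coding_classes <- c("five_prime_ORF", "three_prime_ORF")
  count_groups <- list(); kozak_groups <- list(); len_cor <- list()
  for (cl in coding_classes) {
    ocl <- orfs[category == cl & !is.na(gene_id)]
    host_genes <- rownames(te_mat)
    cnt <- ocl[, .N, by = gene_id]
    n_orfs <- stats::setNames(rep(0L, length(host_genes)), host_genes)
    n_orfs[cnt$gene_id[cnt$gene_id %in% host_genes]] <-
      cnt[gene_id %in% host_genes, N]
    grp <- cut(n_orfs, breaks = c(-1, 0, 1, Inf),
               labels = c("0", "1", "2+"))
    tg <- tukey_groups(gene_mean_te, grp)
    count_groups[[cl]] <- tg

    strong_genes <- unique(ocl[kozak_strong == TRUE, gene_id])
    weak_only <- setdiff(unique(ocl$gene_id), strong_genes)
    kgrp <- ifelse(host_genes %in% strong_genes, "strong_kozak",
                   ifelse(host_genes %in% weak_only, "weak_kozak",
                          "no_orf"))
    kozak_groups[[cl]] <- tukey_groups(gene_mean_te, kgrp)

    ok <- ocl$gene_id %in% names(gene_mean_te)
    if (sum(ok) >= 3L) {
      ct <- suppressWarnings(cor.test(
        (ocl$t_end - ocl$t_start)[ok],
        gene_mean_te[ocl$gene_id[ok]], method = "spearman"))
      len_cor[[cl]] <- data.table::data.table(
        category = cl, rho = unname(ct$estimate), p_value = ct$p.value,
        n = sum(ok))
    }
  }
  list(per_orf = per_orf, count_groups = count_groups,
       kozak_groups = kozak_groups,
       length_correlation = data.table::rbindlist(len_cor))
}
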