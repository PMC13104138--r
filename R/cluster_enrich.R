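#' Max-normalize TE profiles for clustering
#'
#' Keeps genes whose minimum value across stages exceeds `min_value`,
#' then divides each gene's profile by its maximum so every row lies in
#' (0, 1] with at least one stage at exactly 1. All-zero rows (possible
#' only when `min_value < 0`) are excluded and recorded.
#'
#' @param te a `TEProfile` or a gene x stage matrix.
#' @param min_value row-minimum filter (exclusive; default 1).
#' @return normalized matrix with attributes `excluded` (all-zero rows)
#'   and `n_filtered` (rows failing the minimum filter).
#' @export
normalize_profiles <- function(te, min_value = 1) {
  m <- if (inherits(te, "TEProfile")) te$te else te
  keep <- apply(m, 1L, min) > min_value
  m2 <- m[keep, , drop = FALSE]
  mx <- apply(m2, 1L, max)
  zero <- mx == 0
  out <- m2[!zero, , drop = FALSE] / mx[!zero]
  attr(out, "excluded") <- rownames(m2)[zero]
  attr(out, "n_filtered") <- sum(!keep)
  out
}

# seeded k-means++ initial centers
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(NA_real_, k, ncol(m))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- m[idx, ]
  d2 <- rowSums((m - matrix(centers[1L, ], n, ncol(m), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- m[idx, ]
    d2 <- pmin(d2, rowSums((m - matrix(centers[j, ], n, ncol(m),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Seeded k-means clustering of TE profiles
#'
#' Deterministic k-means (seeded k-means++ initialization, Lloyd
#' iterations with a fixed cap). A cluster is called phase-specific when
#' the stage of its centroid maximum falls in one phase and the
#' centroid mean over that phase exceeds the mean over the remaining
#' stages by at least `margin`.
#'
#' @param m normalized gene x stage matrix ([normalize_profiles()]).
#' @param k number of clusters (default 18).
#' @param max_iter Lloyd iteration cap (default 30).
#' @param seed RNG seed for initialization (default 19960912).
#' @param phase_map optional named character stage -> phase enabling
#'   phase assignment.
#' @param margin phase-specificity margin (default 0.2).
#' @return a `ClusterResult`: list with `k`, `seed`, `max_iter`,
#'   `assignments` (named integer), `centroids` (k x stages),
#'   `tot_withinss`, `sizes`, and `phase` (data.table, `NA` phase when
#'   not phase-specific; `NULL` without `phase_map`).
#' @export
kmeans_te <- function(m, k = 18L, max_iter = 30L, seed = 19960912,
                      phase_map = NULL, margin = 0.2) {
  assert_that(nrow(m) >= k, "fewer rows than clusters requested")
  set.seed(seed)
  centers <- kmeanspp_centers(m, k)
  fit <- suppressWarnings(kmeans(m, centers = centers,
                                 iter.max = max_iter,
                                 algorithm = "Lloyd"))
  phase <- NULL
  if (!is.null(phase_map)) {
    stages <- colnames(m)
    phase <- data.table::rbindlist(lapply(seq_len(k), function(cl) {
      cen <- fit$centers[cl, ]
      pmax_stage <- stages[which.max(cen)]
      p <- unname(phase_map[pmax_stage])
      inp <- stages[phase_map[stages] == p]
      outp <- setdiff(stages, inp)
      specific <- length(outp) > 0L &&
        mean(cen[inp]) - mean(cen[outp]) >= margin
      data.table::data.table(cluster = cl,
                             phase = if (specific) p else NA_character_,
                             peak_stage = pmax_stage)
    }))
  }
  structure(list(k = k, seed = seed, max_iter = max_iter,
                 assignments = fit$cluster,
                 centroids = fit$centers,
                 tot_withinss = fit$tot.withinss,
                 sizes = fit$size, phase = phase),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult: k =", x$k, "over", length(x$assignments),
      "genes; total within-SS =", signif(x$tot_withinss, 5), "\n")
  invisible(x)
}

#' Hierarchical clustering of stages
#'
#' UPGMA (average linkage) on Euclidean distances between stage columns.
#' Ties are resolved by `stats::hclust`'s deterministic column order.
#'
#' @param m gene x stage matrix (stages are clustered).
#' @return list with `hclust` (the fitted tree) and `newick` (Newick
#'   string with branch lengths).
#' @export
hclust_stages <- function(m) {
  assert_that(ncol(m) >= 2L, "need at least 2 stage columns")
  hc <- hclust(dist(t(m), method = "euclidean"), method = "average")
  list(hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Hypergeometric enrichment of gene sets
#'
#' For each (set, term) pair, tests over-representation with the
#' upper-tail hypergeometric probability `P[X >= k]` for
#' `X ~ Hypergeometric(N, K, n)` (`N` background size, `K` term genes in
#' the background, `n` set size, `k` term genes in the set), with
#' Benjamini-Hochberg adjustment across terms within each set.
#' Significance stars follow the raw p-value (`*` < 0.05, `**` < 0.01).
#'
#' @param sets named list of gene-id vectors (or a single character
#'   vector), each a subset of `background`.
#' @param terms data.table/data.frame with columns `term`, `gene_id`.
#' @param background character vector, the gene universe.
#' @return data.table `set_id`, `term`, `k`, `K`, `n`, `N`, `p`,
#'   `p_adj`, `stars`.
#' @export
hypergeom_enrich <- function(sets, terms, background) {
  assert_that(length(background) > 0L, "empty background")
  if (!is.list(sets)) sets <- list(set1 = sets)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  terms <- data.table::as.data.table(terms)
  terms <- terms[gene_id %in% background]
  background <- unique(background)
  N <- length(background)
  term_genes <- split(terms$gene_id, terms$term)
  out <- data.table::rbindlist(lapply(names(sets), function(sid) {
    set <- unique(sets[[sid]])
    assert_that(all(set %in% background),
                paste("set", sid, "not a subset of the background"))
    n <- length(set)
    res <- data.table::rbindlist(lapply(names(term_genes), function(tm) {
      tg <- unique(term_genes[[tm]])
      K <- length(tg)
      k <- length(intersect(set, tg))
      p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
      data.table::data.table(set_id = sid, term = tm, k = k, K = K,
                             n = n, N = N, p = p)
    }))
    if (nrow(res) == 0L) {
      res <- data.table::data.table(set_id = character(),
                                    term = character(), k = integer(),
                                    K = integer(), n = integer(),
                                    N = integer(), p = numeric())
    }
    res[, p_adj := stats::p.adjust(p, method = "BH")]
    res
  }))
  out[, stars := data.table::fcase(p < 0.01, "**", p < 0.05, "*",
                                   default = "")]
  out[]
}
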