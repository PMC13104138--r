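`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Mode of an integer vector; ties broken toward `prefer` if tied, else the
# smallest tied value.
stat_mode <- function(x, prefer = NULL) {
  if (length(x) == 0L) return(NA_integer_)
  tab <- table(x)
  best <- as.integer(names(tab)[tab == max(tab)])
  if (!is.null(prefer) && prefer %in% best) return(as.integer(prefer))
  min(best)
}

# Compact letter display from a symmetric logical matrix `sig` where
# sig[i, j] == TRUE means groups i and j differ significantly.
# Insert-and-absorb: start with one letter covering all groups, split on
# each significant pair, then drop letter sets contained in another.
cld_letters <- function(sig) {
  stopifnot(is.matrix(sig), nrow(sig) == ncol(sig))
  g <- nrow(sig)
  if (g == 1L) return(stats::setNames("a", rownames(sig)))
  sets <- list(seq_len(g))
  for (i in seq_len(g - 1L)) {
    for (j in seq.int(i + 1L, g)) {
      if (!isTRUE(sig[i, j])) next
      for (s in seq_along(sets)) {
        if (i %in% sets[[s]] && j %in% sets[[s]]) {
          sets[[s + length(sets)]] <- setdiff(sets[[s]], j)
          sets[[s]] <- setdiff(sets[[s]], i)
        }
      }
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) {
        for (b in seq_along(sets)) {
          if (a != b && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
              (length(sets[[a]]) < length(sets[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      sets <- sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, min, 1L))]
  out <- vapply(seq_len(g), function(i) {
    paste(letters[which(vapply(sets, function(s) i %in% s, TRUE))],
          collapse = "")
  }, character(1))
  stats::setNames(out, rownames(sig))
}

# md5 checksums of a set of files, named by basename, sorted for stable
# manifest comparison.
file_checksums <- function(paths) {
  paths <- sort(paths)
  sums <- tools::md5sum(paths)
  stats::setNames(unname(sums), basename(paths))
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
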