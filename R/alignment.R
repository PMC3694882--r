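# symbol score matrix over codes A,C,G,T,N,-: match/mismatch on ACGT,
# N and gap are neutral (0)
symbol_score_matrix <- function(match, mismatch) {
  M <- matrix(0, 6, 6)
  M[1:4, 1:4] <- mismatch
  diag(M)[1:4] <- match
  M
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman–Wunsch with Gotoh's three-state affine-gap recursion. A gap of
#' length k costs `gap_open + k * gap_extend`. `N` is neutral: it scores 0
#' against anything. Tie-breaking is deterministic: diagonal, then up (gap
#' in `b`), then left.
#'
#' @param a,b Sequence strings over `{A,C,G,T,N}` (non-empty).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters. Defaults
#'   (+1/-1, open 2, extend 0.5) suit short, divergent spacer sequences.
#' @return An object of class `pairwise_alignment`: list with gapped
#'   strings `a` and `b` and the optimal `score`.
#' @export
needleman_wunsch <- function(a, b, match = 1, mismatch = -1,
                             gap_open = 2, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  ca <- encode_seq(a); cb <- encode_seq(b)
  res <- nw_align_cpp(ca, cb, match, mismatch, gap_open, gap_extend)
  ai <- bi <- 0L
  achr <- strsplit(a, "")[[1]]; bchr <- strsplit(b, "")[[1]]
  ga <- gb <- character(length(res$ops))
  for (k in seq_along(res$ops)) {
    op <- res$ops[k]
    if (op == 0L) { ai <- ai + 1L; bi <- bi + 1L
      ga[k] <- achr[ai]; gb[k] <- bchr[bi]
    } else if (op == 1L) { ai <- ai + 1L; ga[k] <- achr[ai]; gb[k] <- "-"
    } else { bi <- bi + 1L; ga[k] <- "-"; gb[k] <- bchr[bi] }
  }
  structure(list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$a, "\n", x$b, "\n", "score: ", x$score, "\n", sep = "")
  invisible(x)
}

#' Smith–Waterman local alignment score
#'
#' Exact best local-alignment score with affine gaps (same gap-cost
#' convention as [needleman_wunsch()]). Used by the BLAST1-style
#' identifier; defaults mirror BLASTN scoring (+2/-3, gap open 5,
#' extend 2).
#'
#' @inheritParams needleman_wunsch
#' @return The optimal local score (>= 0).
#' @export
smith_waterman_score <- function(a, b, match = 2, mismatch = -3,
                                 gap_open = 5, gap_extend = 2) {
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  sw_score_cpp(encode_seq(a), encode_seq(b), match, mismatch,
               gap_open, gap_extend)
}

# mismatch fraction between two unaligned sequences, over columns where
# both carry a proper base after global alignment
nw_mismatch_fraction <- function(a, b, ...) {
  aln <- needleman_wunsch(a, b, ...)
  x <- encode_seq(aln$a); y <- encode_seq(aln$b)
  comp <- x < 4L & y < 4L
  if (!any(comp)) return(1)
  mean(x[comp] != y[comp])
}

# UPGMA with deterministic tie-breaking (smallest pair of original record
# indices); returns merge list for guide-tree traversal
upgma_merges <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))        # clusters as index vectors
  sizes <- rep(1L, n)
  reps <- seq_len(n)                   # smallest original index per cluster
  merges <- list()
  while (length(active) > 1L) {
    m <- length(active)
    best <- NULL
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      dij <- D[i, j]
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (min(reps[i], reps[j]) < min(reps[best$i], reps[best$j]) ||
            (min(reps[i], reps[j]) == min(reps[best$i], reps[best$j]) &&
             max(reps[i], reps[j]) < max(reps[best$i], reps[best$j])))))
        best <- list(i = i, j = j, d = dij)
    }
    i <- best$i; j <- best$j
    merges[[length(merges) + 1L]] <- c(i, j)
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    sizes <- c(sizes[keep], ni + nj)
    reps <- c(reps[keep], min(reps[i], reps[j]))
  }
  list(merges = merges)
}

# column base counts (6 x width) of a profile given integer-coded rows
profile_counts <- function(rows_int) {
  apply(rows_int, 2, tabulate, nbins = 6)  # codes 0..5 -> bins 1..6 via +1
}

#' Progressive multiple sequence alignment
#'
#' Clustal-style progressive alignment: pairwise Needleman–Wunsch
#' mismatch-fraction distances, a UPGMA guide tree (ties broken by the
#' smallest pair of input indices), then leaf-to-root profile–profile
#' alignment scoring columns by the average sum of pairwise symbol scores.
#' Row order of the result equals input order.
#'
#' @param seqs A tibble with `sample_id` and `bases` columns, or a named
#'   character vector of sequences. At least two sequences.
#' @inheritParams needleman_wunsch
#' @return A tibble with the input identifier columns plus `seq`, the
#'   gapped alignment row; alignment width as attribute `width`.
#' @export
progressive_msa <- function(seqs, match = 1, mismatch = -1,
                            gap_open = 2, gap_extend = 0.5) {
  if (is.character(seqs))
    seqs <- tibble::tibble(sample_id = names(seqs) %||%
                             paste0("s", seq_along(seqs)), bases = unname(seqs))
  n <- nrow(seqs)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  bases <- seqs$bases
  if (n == 2L) {
    pw <- needleman_wunsch(bases[1], bases[2], match, mismatch,
                           gap_open, gap_extend)
    rows <- c(pw$a, pw$b)
  } else {
    D <- matrix(0, n, n)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- nw_mismatch_fraction(bases[i], bases[j], match,
                                                 mismatch, gap_open, gap_extend)
    g <- upgma_merges(D)
    M6 <- symbol_score_matrix(match, mismatch)
    # profiles: list of (indices, gapped integer-row matrix)
    profs <- lapply(seq_len(n), function(i)
      list(idx = i, rows = matrix(encode_seq(bases[i]), nrow = 1)))
    for (mg in g$merges) {
      A <- profs[[mg[1]]]; B <- profs[[mg[2]]]
      CA <- profile_counts(A$rows); CB <- profile_counts(B$rows)
      S <- t(CA) %*% M6 %*% CB / (nrow(A$rows) * nrow(B$rows))
      path <- profile_nw_cpp(S, gap_open, gap_extend)$ops
      wa <- ncol(A$rows); wb <- ncol(B$rows)
      newA <- matrix(5L, nrow(A$rows), length(path))
      newB <- matrix(5L, nrow(B$rows), length(path))
      ia <- ib <- 0L
      for (k in seq_along(path)) {
        op <- path[k]
        if (op != 2L) { ia <- ia + 1L; newA[, k] <- A$rows[, ia] }
        if (op != 1L) { ib <- ib + 1L; newB[, k] <- B$rows[, ib] }
      }
      merged <- list(idx = c(A$idx, B$idx), rows = rbind(newA, newB))
      profs <- c(profs[-mg], list(merged))
    }
    final <- profs[[1]]
    rows <- character(n)
    rows[final$idx] <- apply(final$rows, 1, decode_seq)
  }
  out <- seqs
  out$bases <- NULL
  out$seq <- rows
  attr(out, "width") <- nchar(rows[1])
  out
}
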