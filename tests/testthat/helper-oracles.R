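# Independent oracles used across the suite. These deliberately avoid the
# package's DP/Viterbi code paths: alignment scores come from exhaustive
# path enumeration, tree splits from direct edge-matrix traversal.

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive global affine-gap alignment score by path enumeration
# (gap of length k costs open + k * ext; N neutral)
bf_global_score <- function(a, b, match = 1, mismatch = -1,
                            open = 2, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  sub <- function(x, y) {
    if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
  }
  rec <- function(i, j, last, sc) {
    if (i == na && j == nb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i < na && j < nb)
      rec(i + 1, j + 1, "d", sc + sub(av[i + 1], bv[j + 1]))
    if (i < na)
      rec(i + 1, j, "u", sc - if (last == "u") ext else open + ext)
    if (j < nb)
      rec(i, j + 1, "l", sc - if (last == "l") ext else open + ext)
  }
  rec(0, 0, "d", 0)
  best
}

# exhaustive local score: best global score over all substring pairs
bf_local_score <- function(a, b, match = 2, mismatch = -3,
                           open = 5, ext = 2) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i in seq_len(na)) for (j in i:na)
    for (k in seq_len(nb)) for (l in k:nb) {
      s <- bf_global_score(substr(a, i, j), substr(b, k, l),
                           match, mismatch, open, ext)
      if (s > best) best <- s
    }
  best
}

# forced global profile-to-substring log2-odds score, written as a compact
# standalone DP over (match-state, consumed-chars); used by the exhaustive
# substring scan that cross-checks the package's local Viterbi
oracle_profile_global <- function(sub, hmm) {
  codes <- strsplit(sub, "")[[1]]
  n <- length(codes)
  L <- hmm$length
  p <- hmm$p_indel
  lMM <- log2(1 - 2 * p); lMI <- log2(p); lMD <- log2(p)
  lIM <- log2(1 - p); lII <- log2(p)
  lDM <- log2(1 - p); lDD <- log2(p)
  lBM <- log2(1 - p); lBD <- log2(p)
  e <- function(j, ch) {
    if (ch == "N") 0 else log2(hmm$emissions[j, ch] / 0.25)
  }
  M <- matrix(-Inf, L, n + 1); I <- matrix(-Inf, L, n + 1)
  D <- matrix(-Inf, L, n + 1)
  D[1, 1] <- lBD
  if (L > 1) for (j in 2:L) D[j, 1] <- D[j - 1, 1] + lDD
  for (i in seq_len(n)) {
    ci <- i + 1
    for (j in seq_len(L)) {
      M[j, ci] <- e(j, codes[i]) +
        if (j == 1) { if (i == 1) lBM else -Inf } else
          max(M[j - 1, ci - 1] + lMM, I[j - 1, ci - 1] + lIM,
              D[j - 1, ci - 1] + lDM)
      D[j, ci] <- if (j == 1) -Inf else
        max(M[j - 1, ci] + lMD, D[j - 1, ci] + lDD)
      if (j < L)
        I[j, ci] <- max(M[j, ci - 1] + lMI, I[j, ci - 1] + lII)
    }
  }
  max(M[L, n + 1], D[L, n + 1])
}

# exhaustive scan: best (score, interval) over all substrings
oracle_best_flank <- function(sequence, hmm) {
  n <- nchar(sequence)
  best <- list(start = 0L, end = 0L, bits = -Inf)
  for (i in seq_len(n)) for (j in i:n) {
    s <- oracle_profile_global(substr(sequence, i, j), hmm)
    if (s > best$bits) best <- list(start = i - 1L, end = j, bits = s)
  }
  best
}

# bipartitions of a phylo tree by direct edge-matrix traversal
bf_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  edges <- tree$edge
  tips_below <- function(node) {
    if (node <= n) return(node)
    kids <- edges[edges[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    child <- edges[e, 2]
    if (child <= n) next
    side <- sort(tree$tip.label[tips_below(child)])
    if (length(side) < 2 || length(side) > n - 2) next
    anchor <- min(tree$tip.label)
    if (anchor %in% side)
      side <- sort(setdiff(tree$tip.label, side))
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

# canonical bipartition key, reimplemented for test use
canon_key <- function(tips, all_labels) {
  anchor <- min(all_labels)
  side <- if (anchor %in% tips) setdiff(all_labels, tips) else tips
  paste(sort(side), collapse = "|")
}

# two-species toy dataset with a strict gap, used by several modules
toy_gap_seqs <- function() {
  tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    species = c("SpA", "SpA", "SpB", "SpB"),
    bases = c("ACGTACGTACGTACGTACGT",
              "ACGTACGTACGTACGTACGA",
              "TGCATGCATGCATGCATGCA",
              "TGCATGCATGCATGCATGCC"))
}
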