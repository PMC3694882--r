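#' Build a profile HMM for a conserved flank
#'
#' Trains a small match/insert/delete profile from an alignment of the
#' conserved region bordering ITS2 (the 5.8S 3' end or the 28S 5' end).
#' Alignment columns with more than 50% gaps are dropped; match-state
#' emission probabilities are maximum-likelihood counts with an additive
#' pseudocount. Insert and delete transitions share one global probability
#' each (training alignments are far too small to estimate per-position
#' values).
#'
#' @param aligned Character vector of >= 2 equal-length aligned sequences
#'   (gaps as `-`).
#' @param pseudocount Additive smoothing count per base (default 0.5).
#' @param name Model name, e.g. `"5.8S-3'"`.
#' @param p_indel Global insert-open and delete-open probability.
#' @return An object of class `flank_hmm`: emission matrix (match states x
#'   A,C,G,T), model length and transition parameters.
#' @export
build_flank_hmm <- function(aligned, pseudocount = 0.5, name = "flank",
                            p_indel = 0.05) {
  if (length(aligned) < 2L) stop("need >= 2 training sequences", call. = FALSE)
  if (length(unique(nchar(aligned))) != 1L)
    stop("training sequences must be aligned (equal length)", call. = FALSE)
  rows <- do.call(rbind, strsplit(toupper(aligned), ""))
  gap_frac <- colMeans(rows == "-")
  keep <- gap_frac <= 0.5
  if (!any(keep)) stop("no match columns left after gap filtering",
                       call. = FALSE)
  rows <- rows[, keep, drop = FALSE]
  L <- ncol(rows)
  emis <- matrix(pseudocount, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (j in seq_len(L)) {
    cnt <- table(factor(rows[, j], levels = c("A", "C", "G", "T")))
    emis[j, ] <- emis[j, ] + as.numeric(cnt)
  }
  emis <- emis / rowSums(emis)
  structure(list(name = name, emissions = emis, length = L,
                 p_indel = p_indel),
            class = "flank_hmm")
}

#' @export
print.flank_hmm <- function(x, ...) {
  cat("<flank_hmm> ", x$name, ": ", x$length, " match states, p_indel = ",
      x$p_indel, "\n", sep = "")
  invisible(x)
}

#' Write / read a flank profile model
#'
#' Plain-text exchange format: a header with the name, length and indel
#' probability, then one line of A/C/G/T emission probabilities per match
#' state.
#'
#' @param hmm A `flank_hmm`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `flank_hmm` for the reader.
#' @export
write_flank_hmm <- function(hmm, path) {
  lines <- c(paste("name", hmm$name, sep = "\t"),
             paste("length", hmm$length, sep = "\t"),
             paste("p_indel", format(hmm$p_indel, digits = 12), sep = "\t"),
             "A\tC\tG\tT",
             apply(hmm$emissions, 1, function(r)
               paste(format(r, digits = 12), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_flank_hmm
#' @export
read_flank_hmm <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[1:3], "\t", fixed = TRUE)
  L <- as.integer(kv[[2]][2])
  emis <- do.call(rbind, lapply(lines[5:(4 + L)], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  colnames(emis) <- c("A", "C", "G", "T")
  structure(list(name = kv[[1]][2], emissions = emis, length = L,
                 p_indel = as.numeric(kv[[3]][2])),
            class = "flank_hmm")
}

#' Default flank models bundled with the package
#'
#' Profiles built from small synthetic alignments of the canonical
#' conserved plant motifs at the 5.8S 3' end and the 28S 5' end (the
#' regions targeted by the universal ITS3/ITS4 primers). They are
#' constructed stand-ins, adequate for locating the flank boundaries, not
#' curated rRNA models; supply your own alignments to [build_flank_hmm()]
#' for production annotation.
#'
#' @return A list with elements `hmm_58s` and `hmm_28s`.
#' @export
default_flank_hmms <- function() {
  f58 <- system.file("extdata", "flank_58s_synthetic.fasta",
                     package = "barcodegap", mustWork = TRUE)
  f28 <- system.file("extdata", "flank_28s_synthetic.fasta",
                     package = "barcodegap", mustWork = TRUE)
  list(hmm_58s = build_flank_hmm(as.character(Biostrings::readBStringSet(f58)),
                                 name = "5.8S-3'"),
       hmm_28s = build_flank_hmm(as.character(Biostrings::readBStringSet(f28)),
                                 name = "28S-5'"))
}

# log2-odds Viterbi of the profile against the best-scoring subsequence:
# local in the sequence (free background flanks), glocal in the profile
# (every match state is visited or deleted). Background = equal base
# frequencies, so insert states and unmodelled sequence contribute 0 bits.
viterbi_flank <- function(codes, hmm) {
  L <- hmm$length
  n <- length(codes)
  p <- hmm$p_indel
  lMM <- log2(1 - 2 * p); lMI <- log2(p); lMD <- log2(p)
  lIM <- log2(1 - p); lII <- log2(p)
  lDM <- log2(1 - p); lDD <- log2(p)
  lBM <- log2(1 - p); lBD <- log2(p)
  # emission log-odds per (state, char); N emits at background (0 bits)
  E <- cbind(log2(hmm$emissions / 0.25), N = 0)
  NEG <- -Inf
  # columns indexed i = 0..n (chars consumed); start[..] = 1-based index of
  # the first emitted character on the best path
  vM <- matrix(NEG, L, n + 1); sM <- matrix(NA_integer_, L, n + 1)
  vI <- matrix(NEG, L, n + 1); sI <- matrix(NA_integer_, L, n + 1)
  vD <- matrix(NEG, L, n + 1); sD <- matrix(NA_integer_, L, n + 1)
  echar <- ifelse(codes == 4L, 5L, codes + 1L)  # column of E (N -> col 5)
  vD[1, 1] <- lBD; sD[1, 1] <- 1L
  if (L > 1) for (j in 2:L) {  # pure-delete prefix before any character
    vD[j, 1] <- vD[j - 1, 1] + lDD
    sD[j, 1] <- 1L
  }
  for (i in 1:n) {
    ci <- i + 1L
    for (j in 1:L) {
      e <- E[j, echar[i]]
      if (j == 1L) {
        vM[1, ci] <- e + lBM; sM[1, ci] <- i
      } else {
        cand <- c(vM[j - 1, ci - 1] + lMM, vI[j - 1, ci - 1] + lIM,
                  vD[j - 1, ci - 1] + lDM)
        k <- which.max(cand)
        vM[j, ci] <- e + cand[k]
        sM[j, ci] <- switch(k, sM[j - 1, ci - 1], sI[j - 1, ci - 1],
                            sD[j - 1, ci - 1])
      }
      # delete state j at i chars consumed
      if (j == 1L) {
        vD[1, ci] <- lBD; sD[1, ci] <- i + 1L
      } else {
        cand <- c(vM[j - 1, ci] + lMD, vD[j - 1, ci] + lDD)
        k <- which.max(cand)
        vD[j, ci] <- cand[k]
        sD[j, ci] <- if (k == 1L) sM[j - 1, ci] else sD[j - 1, ci]
      }
      if (j < L) {
        cand <- c(vM[j, ci - 1] + lMI, vI[j, ci - 1] + lII)
        k <- which.max(cand)
        vI[j, ci] <- cand[k]
        sI[j, ci] <- if (k == 1L) sM[j, ci - 1] else sI[j, ci - 1]
      }
    }
  }
  ends <- pmax(vM[L, ], vD[L, ])
  best_i <- which.max(ends)
  use_m <- vM[L, best_i] >= vD[L, best_i]
  bits <- ends[best_i]
  start1 <- if (use_m) sM[L, best_i] else sD[L, best_i]
  end0 <- best_i - 1L                     # chars consumed = 0-based exclusive end
  list(start = start1 - 1L, end = end0, bits = bits)
}

#' Locate a conserved flank in a sequence
#'
#' Viterbi-aligns the profile to the best-scoring subsequence (local in the
#' sequence, glocal in the profile) and reports the matched interval and
#' its log2-odds score against an equal-frequency background.
#'
#' @param sequence A single sequence string over `{A,C,G,T,N}`.
#' @param hmm A `flank_hmm`.
#' @return A list with `start` (0-based inclusive), `end` (0-based
#'   exclusive) and `bits`.
#' @export
locate_flank <- function(sequence, hmm) {
  codes <- encode_seq(sequence)
  if (length(codes) < hmm$length / 2)
    stop("sequence shorter than half the profile length", call. = FALSE)
  viterbi_flank(codes, hmm)
}

#' Excise ITS2 by trimming the conserved 5.8S and 28S flanks
#'
#' For each record, both flank profiles are located; the ITS2 proper is the
#' run of bases strictly after the 5.8S match and strictly before the 28S
#' match. Records where either flank scores below `min_bits` are returned
#' untrimmed with status `"untrimmed-low-score"`. A 5.8S match that ends at
#' or after the 28S match start is an overlapping (or swapped) annotation
#' and raises an error naming the record.
#'
#' @param seqs A tibble with `sample_id` and `bases` columns (e.g. from
#'   [read_fasta()]).
#' @param hmm_58s,hmm_28s Flank models; default to [default_flank_hmms()].
#' @param min_bits Minimum flank score, in bits, to accept an annotation.
#' @return The input tibble with `bases` replaced by the trimmed ITS2 where
#'   trimming succeeded, plus columns `status`
#'   (`"trimmed"`/`"untrimmed-low-score"`), `its2_start`, `its2_end`
#'   (1-based inclusive coordinates on the input sequence, `NA` when
#'   untrimmed) and the two flank bit scores.
#' @export
trim_its2 <- function(seqs, hmm_58s = NULL, hmm_28s = NULL, min_bits = 10) {
  if (is.null(hmm_58s) || is.null(hmm_28s)) {
    defaults <- default_flank_hmms()
    hmm_58s <- hmm_58s %||% defaults$hmm_58s
    hmm_28s <- hmm_28s %||% defaults$hmm_28s
  }
  res <- purrr::map2(seqs$bases, seqs$sample_id, function(b, id) {
    loc58 <- locate_flank(b, hmm_58s)
    loc28 <- locate_flank(b, hmm_28s)
    if (loc58$bits < min_bits || loc28$bits < min_bits) {
      return(list(bases = b, status = "untrimmed-low-score",
                  its2_start = NA_integer_, its2_end = NA_integer_,
                  bits_58s = loc58$bits, bits_28s = loc28$bits))
    }
    if (loc58$end >= loc28$start)
      stop("overlapping flank annotation for '", id,
           "': 5.8S match end (", loc58$end, ") >= 28S match start (",
           loc28$start, ")", call. = FALSE)
    list(bases = substr(b, loc58$end + 1L, loc28$start),
         status = "trimmed",
         its2_start = loc58$end + 1L, its2_end = loc28$start,
         bits_58s = loc58$bits, bits_28s = loc28$bits)
  })
  out <- seqs
  out$bases <- purrr::map_chr(res, "bases")
  out$status <- purrr::map_chr(res, "status")
  out$its2_start <- purrr::map_int(res, "its2_start")
  out$its2_end <- purrr::map_int(res, "its2_end")
  out$bits_58s <- purrr::map_dbl(res, "bits_58s")
  out$bits_28s <- purrr::map_dbl(res, "bits_28s")
  out
}
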