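#' Default per-species sample counts at the study scale
#'
#' A fixed profile of 34 species with 1 to 8 samples each, 103 samples in
#' total — the sampling structure of a typical regional barcoding study of
#' a single genus. The exact per-species breakdown is a package choice
#' (only the range and the total are fixed by the emulated design).
#'
#' @return Integer vector of length 34 summing to 103.
#' @export
study_scale_samples <- function() {
  c(8L, 7L, 6L, 6L, 5L, 5L, 4L, 4L, rep(3L, 10), rep(2L, 12), rep(1L, 4))
}

#' Configuration for the barcode dataset simulator
#'
#' @param n_species Number of species.
#' @param samples_per_species Single integer (same count for every
#'   species) or an integer vector of length `n_species`. `NULL` uses
#'   [study_scale_samples()] when `n_species == 34`, otherwise counts are
#'   drawn uniformly from 1..8 with the dataset seed.
#' @param length_range ITS2 length range in nt (default 145–189).
#' @param gc_range GC content window (default 0.46–0.67).
#' @param d_inter Target K2P distance between samples of different species
#'   (default 0.25, the minimum interspecific depth being emulated).
#' @param d_intra Target K2P distance between conspecific samples
#'   (default 0.03).
#' @param kappa Transition/transversion rate ratio alpha/beta (default 2).
#' @param tree_shape `"star"` (no deep structure between species; the
#'   default, because the distance summaries — not tree shape — are the
#'   simulation target) or `"coalescent"` (random species tree, for
#'   monophyly tests).
#' @param flanks Prepend/append the conserved 5.8S/28S flank motifs so the
#'   trimming stage can be exercised (default FALSE).
#' @param indel_rate Per-sample probability of a short (1–3 nt) deletion,
#'   to exercise alignment and pairwise deletion (default 0: K2P ground
#'   truth is exact only without indels).
#' @param seed Random seed (mandatory).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 34, samples_per_species = NULL,
                              length_range = c(145, 189),
                              gc_range = c(0.46, 0.67),
                              d_inter = 0.25, d_intra = 0.03, kappa = 2,
                              tree_shape = c("star", "coalescent"),
                              flanks = FALSE, indel_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_species >= 2, d_inter >= 0, d_intra >= 0, kappa > 0,
            length_range[1] >= 50, length_range[2] >= length_range[1],
            gc_range[1] > 0, gc_range[2] < 1, indel_rate >= 0,
            indel_rate <= 1)
  if (!is.null(samples_per_species)) {
    if (length(samples_per_species) == 1L)
      samples_per_species <- rep(as.integer(samples_per_species), n_species)
    if (length(samples_per_species) != n_species)
      stop("samples_per_species must be a single count or one per species",
           call. = FALSE)
    stopifnot(all(samples_per_species >= 1))
  } else if (n_species == 34) {
    samples_per_species <- study_scale_samples()
  }
  structure(list(n_species = n_species,
                 samples_per_species = samples_per_species,
                 length_range = length_range, gc_range = gc_range,
                 d_inter = d_inter, d_intra = d_intra, kappa = kappa,
                 tree_shape = tree_shape, flanks = flanks,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Mutate a sequence under the Kimura 2-parameter model
#'
#' Applies per-site substitutions with the exact K2P transition
#' probabilities at total expected distance `d_target` and
#' transition/transversion rate ratio `kappa` (rates alpha for
#' transitions, beta for each transversion, alpha/beta = kappa, scaled so
#' that `(alpha + 2 beta) t = d_target`). `N` and gap characters are left
#' untouched. Uses the current RNG state; seed with [set.seed()] or let
#' [simulate_dataset()] manage seeding.
#'
#' @param sequence Sequence string.
#' @param d_target Expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return The mutated sequence string.
#' @export
mutate_k2p <- function(sequence, d_target, kappa = 2) {
  stopifnot(d_target >= 0, kappa > 0)
  if (d_target == 0) return(sequence)
  codes <- encode_seq(sequence)
  bt <- d_target / (kappa + 2)
  at <- kappa * bt
  e2 <- exp(-4 * bt)
  e1 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e2 - 0.5 * e1
  q_tv <- 0.5 - 0.5 * e2          # both transversions together
  u <- stats::runif(length(codes))
  mut <- codes < 4L               # leave N and gaps alone
  new <- codes
  ts <- mut & u < p_ts
  tv1 <- mut & u >= p_ts & u < p_ts + q_tv / 2
  tv2 <- mut & u >= p_ts + q_tv / 2 & u < p_ts + q_tv
  new[ts] <- bitwXor(codes[ts], 2L)
  new[tv1] <- (codes[tv1] + 1L) %% 4L
  new[tv2] <- (codes[tv2] + 3L) %% 4L
  decode_seq(new)
}

# random sequence of given length with an exact G+C count at the target
random_sequence <- function(len, gc) {
  ngc <- round(len * gc)
  codes <- integer(len)
  gc_pos <- sample.int(len, ngc)
  codes[gc_pos] <- sample(c(1L, 2L), ngc, replace = TRUE)     # C or G
  at_pos <- setdiff(seq_len(len), gc_pos)
  codes[at_pos] <- sample(c(0L, 3L), length(at_pos), replace = TRUE)
  decode_seq(codes)
}

gc_of <- function(s) {
  n_gc <- nchar(gsub("[^GC]", "", s))
  n_gc / nchar(gsub("[^ACGT]", "", s))
}

# redraw a stochastic sequence until its GC lands in the window; the cap
# is generous because the proposal mean sits inside the window
draw_gc_bounded <- function(fun, lo, hi, tries = 200L) {
  for (k in seq_len(tries)) {
    s <- fun()
    g <- gc_of(s)
    if (g >= lo && g <= hi) return(s)
  }
  stop("could not generate a sequence inside the GC window [", lo, ", ",
       hi, "]", call. = FALSE)
}

flank_consensus <- function(hmm) {
  paste(colnames(hmm$emissions)[apply(hmm$emissions, 1, which.max)],
        collapse = "")
}

#' Simulate a barcode dataset with known ground truth
#'
#' Generates species ancestors on a star (or random coalescent) species
#' tree whose branch depths give the configured interspecific K2P
#' distance, then mutates each sample from its species ancestor at half
#' the intraspecific distance, so conspecific pairs sit at `d_intra` and
#' heterospecific pairs at `d_inter` (star) in expectation. Per-species
#' sequence lengths are drawn from the configured range (by truncation of
#' a common-length ancestor, so the substitution ground truth stays
#' exact). Regeneration from the same config is bit-identical.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_dataset`: list with `seqs` (a
#'   tibble: `sample_id`, `species`, `accession`, `bases`) and `truth`
#'   (config echo, root and ancestor sequences, species tree when
#'   coalescent, the ground-truth alignment when it is known exactly —
#'   indels off, flanks off — and the expected intra/inter depths).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ns <- config$n_species
  counts <- config$samples_per_species %||% sample(1:8, ns, replace = TRUE)
  sp_names <- sprintf("Species_%02d", seq_len(ns))
  maxlen <- config$length_range[2]
  # root composition sits at the window midpoint (the typical mean GC of
  # the emulated marker); substitution drift provides the spread
  root <- random_sequence(maxlen, mean(config$gc_range))
  sp_tree <- NULL
  # heterospecific sample pairs traverse two sample branches (d_intra/2
  # each) on top of the species-tree path, so the species depth is reduced
  # by d_intra to keep the sample-to-sample interspecific target at d_inter
  d_sp <- max(config$d_inter - config$d_intra, 0)
  gc_lo_all <- config$gc_range[1]
  gc_hi_all <- config$gc_range[2]
  lens <- config$length_range[1] +
    sample.int(config$length_range[2] - config$length_range[1] + 1L,
               ns, replace = TRUE) - 1L
  # ancestors (already truncated to the species length) are kept at least
  # 0.01 inside the window so the shallow sample mutations rarely reject
  gc_lo_anc <- gc_lo_all + 0.01
  gc_hi_anc <- gc_hi_all - 0.01
  if (config$tree_shape == "star") {
    ancestors <- vapply(seq_len(ns), function(i)
      draw_gc_bounded(function()
        substr(mutate_k2p(root, d_sp / 2, config$kappa), 1L, lens[i]),
        gc_lo_anc, gc_hi_anc), character(1))
  } else {
    sp_tree <- ape::rcoal(ns, tip.label = sp_names)
    coph <- ape::cophenetic.phylo(sp_tree)
    scale <- d_sp / min(coph[upper.tri(coph)])
    sp_tree$edge.length <- sp_tree$edge.length * scale
    # evolve the root sequence down the species tree, preorder
    nodeseq <- vector("list", ape::Ntip(sp_tree) + sp_tree$Nnode)
    rootnode <- ape::Ntip(sp_tree) + 1L
    nodeseq[[rootnode]] <- root
    ord <- ape::reorder.phylo(sp_tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      len <- ord$edge.length[e]
      nodeseq[[child]] <- if (child <= ape::Ntip(sp_tree)) {
        sp_i <- match(sp_tree$tip.label[child], sp_names)
        draw_gc_bounded(function()
          substr(mutate_k2p(nodeseq[[par]], len, config$kappa), 1L,
                 lens[sp_i]),
          gc_lo_anc, gc_hi_anc)
      } else mutate_k2p(nodeseq[[par]], len, config$kappa)
    }
    ancestors <- vapply(seq_len(ns), function(i)
      nodeseq[[match(sp_names[i], sp_tree$tip.label)]], character(1))
  }
  names(ancestors) <- sp_names
  f58 <- f28 <- ""
  if (config$flanks) {
    models <- default_flank_hmms()
    f58 <- flank_consensus(models$hmm_58s)
    f28 <- flank_consensus(models$hmm_28s)
  }
  seqs <- purrr::map_dfr(seq_len(ns), function(i) {
    anc <- ancestors[[i]]
    purrr::map_dfr(seq_len(counts[i]), function(j) {
      b <- draw_gc_bounded(function()
        mutate_k2p(anc, config$d_intra / 2, config$kappa),
        gc_lo_all, gc_hi_all)
      if (config$indel_rate > 0 && stats::runif(1) < config$indel_rate) {
        w <- sample(1:3, 1)
        pos <- sample.int(nchar(b) - w, 1)
        b <- paste0(substr(b, 1, pos), substr(b, pos + w + 1L, nchar(b)))
      }
      tibble::tibble(sample_id = sprintf("%s_s%d", sp_names[i], j),
                     species = sp_names[i], accession = NA_character_,
                     bases = paste0(f58, b, f28))
    })
  })
  # with indels off the true alignment is right-padding to equal width;
  # exposed so estimator checks need not depend on the aligner
  truth_aln <- NULL
  if (config$indel_rate == 0 && !config$flanks) {
    w <- max(nchar(seqs$bases))
    truth_aln <- tibble::tibble(
      sample_id = seqs$sample_id, species = seqs$species,
      seq = paste0(seqs$bases,
                   strrep("-", w - nchar(seqs$bases))))
  }
  structure(list(seqs = seqs,
                 truth = list(config = config, root = root,
                              ancestors = ancestors, species_tree = sp_tree,
                              alignment = truth_aln,
                              expected = list(intra = config$d_intra,
                                              inter = config$d_inter))),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ", nrow(x$seqs), " samples, ",
      x$truth$config$n_species, " species (seed ",
      x$truth$config$seed, ")\n", sep = "")
  invisible(x)
}
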