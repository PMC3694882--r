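# canonical bipartition key: the side not containing the anchor label
# (the alphabetically first label), sorted and collapsed
canonical_bipartition <- function(side_labels, all_labels) {
  anchor <- min(all_labels)
  side <- if (anchor %in% side_labels) setdiff(all_labels, side_labels)
          else side_labels
  paste(sort(side), collapse = "|")
}

# Saitou-Nei neighbor joining; returns the newick string, the canonical
# keys of the internal (nontrivial) bipartitions, and a count of negative
# branch lengths. Ties on Q are broken by the lexicographically smallest
# pair of cluster keys (the smallest tip label in each cluster), which
# makes the result invariant to input row order.
nj_core <- function(D, ids) {
  n <- nrow(D)
  fmt <- function(x) sprintf("%.10g", x)
  labs <- ids                       # newick fragment per active cluster
  sets <- as.list(ids)              # tip labels per active cluster
  ckey <- ids                       # smallest member label per cluster
  keys <- character(0)
  n_neg <- 0L
  m <- n
  while (m > 3L) {
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      k1 <- pmin(ckey[cand[, 1]], ckey[cand[, 2]])
      k2 <- pmax(ckey[cand[, 1]], ckey[cand[, 2]])
      cand <- cand[order(k1, k2), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    n_neg <- n_neg + sum(c(vi, vj) < 0)
    newlab <- paste0("(", labs[i], ":", fmt(vi), ",", labs[j], ":",
                     fmt(vj), ")")
    newset <- c(sets[[i]], sets[[j]])
    if (length(newset) >= 2L && length(newset) <= n - 2L)
      keys <- c(keys, canonical_bipartition(newset, ids))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    labs <- c(labs[keep], newlab)
    sets <- c(sets[keep], list(newset))
    ckey <- c(ckey[keep], min(ckey[i], ckey[j]))
    m <- m - 1L
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  n_neg <- n_neg + sum(c(l1, l2, l3) < 0)
  newick <- paste0("(", labs[1], ":", fmt(l1), ",", labs[2], ":", fmt(l2),
                   ",", labs[3], ":", fmt(l3), ");")
  list(newick = newick, keys = unique(keys), n_negative = n_neg)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration on the Q criterion with deterministic
#' tie-breaking (lowest Q, then the lexicographically smallest pair of
#' cluster labels, so the result does not depend on row order), branch
#' lengths
#' from the standard two-point formulas and the three-point formula at the
#' final trifurcation. Negative branch lengths are preserved (so additivity
#' identities hold exactly) and counted in the
#' `n_negative_branches` attribute; set `clamp = TRUE` to truncate them to
#' zero with the length transferred to the sister edge.
#'
#' @param matrix Symmetric matrix of finite distances, n >= 3.
#' @param ids Tip labels; default `rownames(matrix)`.
#' @param clamp Truncate negative branch lengths to zero (default FALSE).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(matrix, ids = rownames(matrix), clamp = FALSE) {
  n <- nrow(matrix)
  if (n < 3L) stop("need at least three taxa", call. = FALSE)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  off <- matrix[upper.tri(matrix)]
  if (any(!is.finite(off))) {
    ut <- which(upper.tri(matrix), arr.ind = TRUE)
    bad <- ut[which(!is.finite(off))[1], ]
    stop("non-finite distance between '", ids[bad[1]], "' and '",
         ids[bad[2]], "'", call. = FALSE)
  }
  res <- nj_core(matrix, ids)
  tree <- ape::read.tree(text = res$newick)
  if (clamp && any(tree$edge.length < 0)) {
    # move the negative amount onto the sister edges through the parent
    for (e in which(tree$edge.length < 0)) {
      amt <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      parent <- tree$edge[e, 1]
      sib <- setdiff(which(tree$edge[, 1] == parent), e)[1]
      tree$edge.length[sib] <- tree$edge.length[sib] + amt
    }
  }
  attr(tree, "n_negative_branches") <- res$n_negative
  tree
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the tips in two; the canonical key of a split
#' is the sorted side not containing the alphabetically first tip label.
#'
#' @param tree An [ape::phylo] object.
#' @return Character vector of canonical bipartition keys.
#' @export
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (k in seq_along(pp)) {
    node <- n + k
    if (node == n + 1L) next                 # root: not an edge
    side <- tree$tip.label[pp[[k]]]
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, canonical_bipartition(side, tree$tip.label))
  }
  unique(keys)
}

#' Neighbor-joining with nonparametric bootstrap support
#'
#' Builds the NJ tree from the full alignment's K2P matrix, then resamples
#' alignment columns with replacement `replicates` times, rebuilding the
#' matrix and tree each time. The support of each internal edge is the
#' percentage of replicates whose tree contains the same bipartition.
#' Replicates in which some pair has no comparable site, or a saturated
#' (infinite) distance, are redrawn; redraws are counted and capped.
#'
#' @param alignment A tibble with `sample_id` and `seq` (gapped) columns,
#'   e.g. from [progressive_msa()].
#' @param replicates Number of bootstrap replicates (>= 1; 1000 is the
#'   conventional choice).
#' @param seed Random seed (mandatory, for reproducibility).
#' @param max_redraws Cap on the total number of redrawn replicates.
#' @return The NJ tree with `node.label` set to integer support
#'   percentages (empty at the root), and attributes `n_redraws` and
#'   `support` (named vector keyed by bipartition).
#' @export
bootstrap_support <- function(alignment, replicates = 1000, seed,
                              max_redraws = 10 * replicates) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(replicates >= 1)
  ids <- alignment$sample_id
  X <- encode_alignment(alignment$seq)
  D <- distance_matrix(alignment)
  main <- nj_core(D, ids)
  tree <- ape::read.tree(text = main$newick)
  counts <- setNames(numeric(length(main$keys)), main$keys)
  set.seed(seed)
  redraws <- 0L
  L <- ncol(X)
  for (b in seq_len(replicates)) {
    repeat {
      idx <- sample.int(L, L, replace = TRUE)
      cnt <- pair_counts_cpp(X[, idx, drop = FALSE])
      sites <- cnt$sites; diag(sites) <- 1L
      if (any(sites == 0L)) { redraws <- redraws + 1L }
      else {
        d <- k2p_distance(list(P = cnt$transitions / sites,
                               Q = cnt$transversions / sites))
        d <- matrix(d, nrow(X), nrow(X)); diag(d) <- 0
        if (all(is.finite(d))) break
        redraws <- redraws + 1L
      }
      if (redraws > max_redraws)
        stop("bootstrap redraw cap exceeded (", max_redraws, ")",
             call. = FALSE)
    }
    keys <- nj_core(d, ids)$keys
    hit <- intersect(keys, names(counts))
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / replicates)
  # map supports onto internal nodes of the main tree
  n <- length(ids)
  pp <- ape::prop.part(tree)
  lab <- character(tree$Nnode)
  for (k in seq_along(pp)) {
    node <- n + k
    if (node == n + 1L) { lab[k] <- ""; next }
    side <- tree$tip.label[pp[[k]]]
    if (length(side) < 2L || length(side) > n - 2L) { lab[k] <- ""; next }
    key <- canonical_bipartition(side, tree$tip.label)
    lab[k] <- if (key %in% names(support)) as.character(support[[key]]) else ""
  }
  tree$node.label <- lab
  attr(tree, "n_redraws") <- redraws
  attr(tree, "support") <- support
  attr(tree, "n_negative_branches") <- main$n_negative
  tree
}

#' Bootstrap support for the clade separating a set of tips
#'
#' Looks up the support of the bipartition that splits exactly `tips`
#' from the remaining leaves of a tree returned by [bootstrap_support()].
#'
#' @param tree A tree with a `support` attribute.
#' @param tips Tip labels of the putative clade.
#' @return Support in percent, or `NA` if the bipartition is not an edge
#'   of the tree.
#' @export
clade_support <- function(tree, tips) {
  sup <- attr(tree, "support")
  if (is.null(sup)) stop("tree carries no bootstrap support", call. = FALSE)
  key <- canonical_bipartition(tips, tree$tip.label)
  if (key %in% names(sup)) unname(sup[[key]]) else NA_real_
}

#' Species monophyly on an unrooted tree
#'
#' A species is monophyletic (in the unrooted sense) when some edge's
#' bipartition separates exactly its samples from everything else.
#' Singletons, and species containing all but one tip, are trivially
#' monophyletic.
#'
#' @param tree An [ape::phylo] tree whose tips are sample ids.
#' @param species Species label per tip: a named vector (names = tip
#'   labels) or a tibble with `sample_id` and `species`.
#' @return A tibble (`species`, `n_samples`, `monophyletic`) with the
#'   percentage of monophyletic species as attribute `pct_monophyletic`.
#' @export
monophyly_check <- function(tree, species) {
  if (is.data.frame(species))
    species <- setNames(species$species, species$sample_id)
  if (is.null(names(species)))
    stop("species must be named by tip label", call. = FALSE)
  labs <- tree$tip.label
  sp <- species[labs]
  if (anyNA(sp)) stop("missing species label for some tips", call. = FALSE)
  keys <- tree_bipartitions(tree)
  n <- length(labs)
  out <- purrr::map_dfr(unique(sp), function(s) {
    tips <- labs[sp == s]
    k <- length(tips)
    mono <- k == 1L || k >= n - 1L ||
      canonical_bipartition(tips, labs) %in% keys
    tibble::tibble(species = s, n_samples = k, monophyletic = mono)
  })
  attr(out, "pct_monophyletic") <- 100 * mean(out$monophyletic)
  out
}
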