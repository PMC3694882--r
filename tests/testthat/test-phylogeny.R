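test_that("NJ reproduces the worked additive 4-taxon case", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4)
  dimnames(D) <- list(LETTERS[1:4], LETTERS[1:4])
  tree <- neighbor_joining(D)
  # topology AB | CD
  expect_true("C|D" %in% tree_bipartitions(tree) ||
                "A|B" %in% tree_bipartitions(tree))
  # the tree reproduces the additive matrix exactly:
  # leaves 1,2,3,4 and internal branch 1
  coph <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(coph, D, tolerance = 1e-9, ignore_attr = TRUE)
  lens <- setNames(tree$edge.length[tree$edge[, 2] <= 4],
                   tree$tip.label[tree$edge[tree$edge[, 2] <= 4, 2]])
  expect_equal(lens[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4))
})

test_that("three taxa use the closed three-point formulas", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3)
  dimnames(D) <- list(c("x", "y", "z"), c("x", "y", "z"))
  tree <- neighbor_joining(D)
  lens <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(lens[["x"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(lens[["y"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(lens[["z"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ recovers random additive trees exactly (n <= 8)", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    true <- ape::unroot(true)
    D <- ape::cophenetic.phylo(true)
    est <- neighbor_joining(D)
    # identical topology ...
    expect_equal(ape::dist.topo(est, true), 0, ignore_attr = TRUE)
    # ... and identical path lengths (additivity preserved to 1e-9)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    # cross-check against the reference NJ implementation
    ref <- ape::nj(D)
    expect_equal(ape::dist.topo(est, ref), 0, ignore_attr = TRUE)
  }
})

test_that("an infinite distance is rejected with the pair named", {
  D <- matrix(0.3, 4, 4); diag(D) <- 0
  D[2, 3] <- D[3, 2] <- Inf
  dimnames(D) <- list(paste0("t", 1:4), paste0("t", 1:4))
  expect_error(neighbor_joining(D), "t2.*t3")
})

test_that("negative branch lengths are flagged and clampable", {
  # a non-additive matrix known to induce a negative NJ branch
  D <- matrix(c(0, 0.1, 0.4, 0.4,
                0.1, 0, 0.4, 0.4,
                0.4, 0.4, 0, 0.02,
                0.4, 0.4, 0.02, 0), 4, 4)
  D[1, 4] <- D[4, 1] <- 0.45
  dimnames(D) <- list(paste0("t", 1:4), paste0("t", 1:4))
  tree <- neighbor_joining(D)
  clamped <- neighbor_joining(D, clamp = TRUE)
  expect_true(all(clamped$edge.length >= 0))
  # total tree length is preserved by the transfer
  expect_equal(sum(clamped$edge.length), sum(tree$edge.length))
})

test_that("bipartition extraction matches brute-force edge traversal", {
  set.seed(52)
  for (i in 1:8) {
    tree <- ape::unroot(ape::rtree(sample(5:9, 1)))
    expect_setequal(tree_bipartitions(tree), bf_bipartitions(tree))
  }
})

test_that("bootstrap gives full support to a clean two-cluster split", {
  ds <- simulate_dataset(simulation_config(
    n_species = 2, samples_per_species = 4, d_intra = 0.01, d_inter = 0.4,
    seed = 53))
  aln <- progressive_msa(ds$seqs)
  tree <- bootstrap_support(aln, replicates = 100, seed = 99)
  key <- canon_key(ds$seqs$sample_id[ds$seqs$species ==
                                                   "Species_02"],
                               ds$seqs$sample_id)
  sup <- attr(tree, "support")
  expect_true(key %in% names(sup))
  expect_gte(sup[[key]], 95)
})

test_that("with a single replicate supports are 0 or 100", {
  ds <- simulate_dataset(simulation_config(
    n_species = 3, samples_per_species = 3, seed = 54))
  aln <- progressive_msa(ds$seqs)
  tree <- bootstrap_support(aln, replicates = 1, seed = 1)
  expect_true(all(attr(tree, "support") %in% c(0, 100)))
})

test_that("bootstrap support is invariant to leaf order", {
  ds <- simulate_dataset(simulation_config(
    n_species = 3, samples_per_species = 3, d_intra = 0.02, d_inter = 0.35,
    seed = 55))
  aln <- progressive_msa(ds$seqs)
  t1 <- bootstrap_support(aln, replicates = 50, seed = 7)
  perm <- sample(nrow(aln))
  t2 <- bootstrap_support(aln[perm, ], replicates = 50, seed = 7)
  s1 <- attr(t1, "support"); s2 <- attr(t2, "support")
  shared <- intersect(names(s1), names(s2))
  expect_true(length(shared) >= 1)
  expect_equal(s1[shared], s2[shared])
})

test_that("identical sequences give a tree with no positive internal edges", {
  aln <- tibble::tibble(sample_id = paste0("s", 1:5),
                        seq = rep("ACGTACGTACGTACGTACGT", 5))
  tree <- bootstrap_support(aln, replicates = 10, seed = 2)
  internal <- tree$edge[, 2] > length(tree$tip.label)
  expect_true(all(abs(tree$edge.length[internal]) < 1e-12))
})

test_that("a fully resolved unrooted tree has n - 3 bipartitions", {
  set.seed(56)
  for (n in 5:8) {
    D <- ape::cophenetic.phylo(ape::rtree(n))
    expect_length(tree_bipartitions(neighbor_joining(D)), n - 3)
  }
})

test_that("monophyly detection matches the bipartition oracle", {
  # caterpillar with contiguous species blocks: all monophyletic
  tree <- ape::read.tree(
    text = "(((a1:1,a2:1):1,(b1:1,b2:1):1):1,(c1:1,c2:1):1,d1:1);")
  sp <- setNames(c("A", "A", "B", "B", "C", "C", "D"),
                 c("a1", "a2", "b1", "b2", "c1", "c2", "d1"))
  res <- monophyly_check(tree, sp)
  expect_true(all(res$monophyletic))
  expect_equal(attr(res, "pct_monophyletic"), 100)

  # swapping one sample between blocks breaks both species
  sp2 <- sp
  sp2[c("a2", "b2")] <- c("B", "A")
  res2 <- monophyly_check(tree, sp2)
  expect_false(res2$monophyletic[res2$species == "A"])
  expect_false(res2$monophyletic[res2$species == "B"])
  expect_true(res2$monophyletic[res2$species == "C"])
  expect_true(res2$monophyletic[res2$species == "D"])  # singleton

  # brute-force check: species leaf set must be a side of some bipartition
  keys <- bf_bipartitions(tree)
  for (s in unique(sp2)) {
    tips <- names(sp2)[sp2 == s]
    expected <- length(tips) == 1 ||
      canon_key(tips, names(sp2)) %in% keys
    expect_equal(res2$monophyletic[res2$species == s], expected)
  }
})
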