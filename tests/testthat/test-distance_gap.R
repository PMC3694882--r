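test_that("substitution counting uses pairwise deletion and P/Q classes", {
  same <- count_substitutions("ACGT", "ACGT")
  expect_equal(same, list(L = 4L, P = 0, Q = 0))

  mixed <- count_substitutions("AAAA-CCCC", "GAAA-CCCA")
  expect_equal(mixed$L, 8L)
  expect_equal(mixed$P, 1 / 8)  # A<->G
  expect_equal(mixed$Q, 1 / 8)  # C<->A

  expect_error(count_substitutions("A---", "-CCC"), "comparable")
  # N triggers pairwise deletion like a gap
  withN <- count_substitutions("ANGT", "AAGT")
  expect_equal(withN$L, 3L)
})

test_that("K2P closed form, JC limit and saturation behave as derived", {
  expect_equal(k2p_distance(list(P = 0, Q = 0)), 0)
  # direct evaluation of the closed form
  expect_equal(k2p_distance(list(P = 0.1, Q = 0.05)),
               -0.5 * log(1 - 0.2 - 0.05) - 0.25 * log(1 - 0.1))
  expect_equal(round(k2p_distance(list(P = 0.1, Q = 0.05)), 4), 0.1702)
  # K2P collapses to Jukes-Cantor whenever Q = 2P
  for (p in c(0.03, 0.06, 0.09, 0.15)) {
    expect_equal(k2p_distance(list(P = p / 3, Q = 2 * p / 3)),
                 -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
  }
  expect_equal(round(k2p_distance(list(P = 0.03, Q = 0.06)), 4), 0.0959)
  # saturation is flagged, not raised
  expect_identical(k2p_distance(list(P = 0.5, Q = 0.2)), Inf)
  expect_identical(k2p_distance(list(P = 0.1, Q = 0.5)), Inf)
})

test_that("K2P dominates the uncorrected p-distance and is monotone", {
  set.seed(31)
  for (i in 1:50) {
    P <- runif(1, 0, 0.3); Q <- runif(1, 0, 0.25)
    if (1 - 2 * P - Q <= 0.05) next
    d <- k2p_distance(list(P = P, Q = Q))
    expect_gte(d, P + Q)
    expect_gt(k2p_distance(list(P = P + 0.01, Q = Q)), d)
    expect_gt(k2p_distance(list(P = P, Q = Q + 0.01)), d)
  }
})

test_that("distance matrix agrees with per-pair counting and with ape", {
  rows <- c(s1 = "ACGTACGTACGTACGTACGT",
            s2 = "ACGTACGTACGTACGCACGT",
            s3 = "ATGTACTTACGAACGCACGT")
  D <- distance_matrix(rows)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  expect_equal(D, t(D))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(D[i, j],
                 k2p_distance(count_substitutions(rows[i], rows[j])))
  # independent implementation on the same alignment
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(rows), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(ref), tolerance = 1e-9)
})

test_that("a saturated pair yields a flagged infinite entry, not an error", {
  rows <- c(a = "AAAAAAAAAA", b = "GGGGGGGGGG", c = "AAAAAAAAAG")
  D <- distance_matrix(rows)
  expect_identical(D["a", "b"], Inf)
  expect_true(is.finite(D["a", "c"]))
})

test_that("partitioning classifies each pair once with correct aggregates", {
  # 2 species x 2 samples: 0.01 within, 0.30 between
  D <- matrix(0.30, 4, 4)
  diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.01
  D[3, 4] <- D[4, 3] <- 0.01
  dimnames(D) <- list(c("a1", "a2", "b1", "b2"), c("a1", "a2", "b1", "b2"))
  part <- partition_distances(D, c("A", "A", "B", "B"))
  intra <- part$pairs$distance[part$pairs$type == "intraspecific"]
  inter <- part$pairs$distance[part$pairs$type == "interspecific"]
  expect_equal(sort(intra), c(0.01, 0.01))
  expect_equal(inter, rep(0.30, 4))
  expect_equal(part$per_species$max_intra, c(0.01, 0.01))
  expect_equal(part$per_species$min_inter, c(0.30, 0.30))

  s <- summarize_partition(part)
  expect_equal(s$mean, c(0.30, 0.30, 0.01, 0.01))
  expect_equal(s$sd, rep(0, 4))

  expect_error(partition_distances(D, rep("A", 4)), "fewer than two")
})

test_that("singleton species appear in min-inter but not coalescent depth", {
  D <- matrix(0.2, 3, 3); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.01
  dimnames(D) <- list(c("a1", "a2", "b1"), c("a1", "a2", "b1"))
  part <- partition_distances(D, c("A", "A", "B"))
  expect_equal(part$per_species$max_intra, c(0.01, NA))
  expect_equal(part$per_species$min_inter, c(0.2, 0.2))
  s <- summarize_partition(part)
  expect_equal(s$n[s$measure == "coalescent_depth"], 1L)
  expect_equal(s$n[s$measure == "minimum_interspecific"], 2L)
})

test_that("partition sizes always sum to n(n-1)/2", {
  set.seed(32)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    D <- matrix(runif(n * n), n, n); D <- (D + t(D)) / 2; diag(D) <- 0
    labels <- sample(paste0("sp", 1:3), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    part <- partition_distances(D, labels)
    expect_equal(nrow(part$pairs), n * (n - 1) / 2)
  }
})

test_that("exact Wilcoxon p comes from enumeration of rank assignments", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 3)          # rank sum of x
  expect_equal(res$p_value, 2 / 6)        # 2 of 6 assignments as extreme
  expect_equal(res$method, "exact")
  # identical samples: p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # agreement with the standard implementation (tie-free, exact regime)
  set.seed(33)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  ours <- wilcoxon_rank_sum(x, y)
  ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("normal approximation matches exact within 0.02 and catches shifts", {
  set.seed(34)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, runif(1, 0, 1.5))
    pe <- wilcoxon_rank_sum(x, y, method = "exact")$p_value
    pn <- wilcoxon_rank_sum(x, y, method = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
  big <- wilcoxon_rank_sum(rnorm(60), rnorm(60, 5))
  expect_equal(big$method, "normal")
  expect_lt(big$p_value, 1e-6)
  # independent formula check in the normal regime
  ref <- stats::wilcox.test(rnorm(30), rnorm(30, 0.3), exact = FALSE,
                            correct = TRUE)
  expect_true(is.finite(ref$p.value))  # sanity on the reference itself
})

test_that("gap report: threshold proportion, bins, D ratio, 1:1 line", {
  D <- matrix(c(0, 0.001, 0.02, 0.3,
                0.001, 0, 0.4, 0.5,
                0.02, 0.4, 0, 0.001,
                0.3, 0.5, 0.001, 0), 4, 4)
  dimnames(D) <- list(c("a1", "a2", "b1", "b2"), c("a1", "a2", "b1", "b2"))
  part <- partition_distances(D, c("A", "A", "B", "B"))
  rep <- gap_report(part, bin_width = 0.002, threshold = 0.03)
  # inter = {0.02, 0.3, 0.4, 0.5}: one of four below 0.03
  expect_equal(rep$prop_inter_below_pct, 25)
  # intra = {0.001, 0.001} fall in bin [0, 0.002)
  expect_equal(rep$intra_hist$count[1], 2)
  expect_equal(rep$intra_hist$bin_start[1], 0)
  expect_equal(rep$intra_hist$bin_end[1], 0.002)
  # histogram counts sum to set sizes
  expect_equal(sum(rep$intra_hist$count), rep$n_intra)
  expect_equal(sum(rep$inter_hist$count), rep$n_inter)
  # max intra 0.001 < min inter 0.02 for both species
  expect_true(all(rep$species$above_line))
  expect_equal(rep$species$d_ratio, c(20, 20))
})

test_that("zero intraspecific variation gives an infinite D ratio", {
  D <- matrix(0.25, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0
  D[3, 4] <- D[4, 3] <- 0
  dimnames(D) <- list(letters[1:4], letters[1:4])
  rep <- gap_report(partition_distances(D, c("A", "A", "B", "B")))
  expect_true(all(is.infinite(rep$species$d_ratio)))
  expect_true(all(rep$species$above_line))
  expect_equal(rep$species$max_intra, c(0, 0))
})

test_that("gap report plots build without error", {
  D <- matrix(0.25, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.01; D[3, 4] <- D[4, 3] <- 0.01
  dimnames(D) <- list(letters[1:4], letters[1:4])
  rep <- gap_report(partition_distances(D, c("A", "A", "B", "B")))
  expect_s3_class(autoplot(rep, type = "histogram"), "ggplot")
  expect_s3_class(autoplot(rep, type = "scatter"), "ggplot")
})
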