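test_that("flank profile emissions are smoothed column counts", {
  # identical training copies, no smoothing: point-mass emissions
  h <- build_flank_hmm(rep("ACGT", 4), pseudocount = 0)
  expect_equal(h$length, 4)
  expect_equal(diag(h$emissions[, c("A", "C", "G", "T")]), rep(1, 4),
               ignore_attr = TRUE)
  # split column without smoothing
  h2 <- build_flank_hmm(c("ACGT", "ACGA"), pseudocount = 0)
  expect_equal(h2$emissions[4, "T"], 0.5, ignore_attr = TRUE)
  expect_equal(h2$emissions[4, "A"], 0.5, ignore_attr = TRUE)
  # Laplace smoothing: (1 + 0.5) / (2 + 4 * 0.5)
  h3 <- build_flank_hmm(c("ACGT", "ACGA"), pseudocount = 0.5)
  expect_equal(h3$emissions[4, "T"], 0.375, ignore_attr = TRUE)
  # rows normalized
  expect_equal(rowSums(h3$emissions), rep(1, 4), tolerance = 1e-9)
})

test_that("majority-gap columns are dropped; empty models are an error", {
  h <- build_flank_hmm(c("A-CG", "A--G", "ATCG"), pseudocount = 0)
  expect_equal(h$length, 3)  # column 2 has 2/3 gaps
  expect_error(build_flank_hmm(c("--", "--"), pseudocount = 0.5),
               "no match columns")
  expect_error(build_flank_hmm("ACGT"), ">= 2")
})

test_that("flank model files round-trip", {
  h <- build_flank_hmm(c("ACGTACGTACGT", "ACGAACGTACGT"), name = "test")
  path <- withr::local_tempfile(fileext = ".hmm")
  write_flank_hmm(h, path)
  back <- read_flank_hmm(path)
  expect_equal(back$emissions, h$emissions, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back$p_indel, h$p_indel)
  expect_equal(back$name, "test")
})

test_that("locate_flank matches the exhaustive substring-scan oracle", {
  set.seed(11)
  motif <- "ACGTTGCAGGAC"
  hmm <- build_flank_hmm(c(motif, motif, "ACGTTGCAGGAT"), pseudocount = 0.5)
  # the motif alone maps to itself
  self <- locate_flank(motif, hmm)
  expect_equal(self$start, 0)
  expect_equal(self$end, nchar(motif))
  for (rep in 1:5) {
    left <- rand_seq(sample(5:20, 1))
    right <- rand_seq(sample(5:20, 1))
    seqn <- paste0(left, motif, right)
    if (nchar(seqn) > 55) next
    got <- locate_flank(seqn, hmm)
    want <- oracle_best_flank(seqn, hmm)
    expect_equal(got$bits, want$bits, tolerance = 1e-9)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # planted coordinates recovered
    expect_equal(got$start, nchar(left))
    expect_equal(got$end, nchar(left) + nchar(motif))
    # reversed motif scores strictly lower than the planted forward match
    rev_seq <- paste0(left, paste(rev(strsplit(motif, "")[[1]]),
                                  collapse = ""), right)
    expect_lt(oracle_best_flank(rev_seq, hmm)$bits, got$bits)
  }
})

test_that("trimming excises exactly the region between the flanks", {
  models <- default_flank_hmms()
  f58 <- "GCATCGATGAAGAACGCAGC"
  f28 <- "GCATATCAATAAGCGGAGGA"
  set.seed(5)
  its2 <- rand_seq(160)
  seqs <- tibble::tibble(sample_id = "s1", species = "Sp",
                         bases = paste0(f58, its2, f28))
  out <- trim_its2(seqs, models$hmm_58s, models$hmm_28s)
  expect_equal(out$status, "trimmed")
  expect_equal(out$bases, its2)
  expect_equal(out$its2_start, nchar(f58) + 1L)      # 1-based inclusive
  expect_equal(out$its2_end, nchar(f58) + nchar(its2))
})

test_that("low-scoring and swapped flanks are handled per contract", {
  models <- default_flank_hmms()
  set.seed(6)
  noflank <- tibble::tibble(sample_id = "r1", species = "Sp",
                            bases = rand_seq(150))
  out <- trim_its2(noflank, models$hmm_58s, models$hmm_28s)
  expect_equal(out$status, "untrimmed-low-score")
  expect_equal(out$bases, noflank$bases)
  expect_true(is.na(out$its2_start))

  swapped <- tibble::tibble(
    sample_id = "sw", species = "Sp",
    bases = paste0("GCATATCAATAAGCGGAGGA", rand_seq(100),
                   "GCATCGATGAAGAACGCAGC"))
  expect_error(trim_its2(swapped, models$hmm_58s, models$hmm_28s),
               "overlapping")
})

test_that("trimming is idempotent: a trimmed ITS2 has no flanks left", {
  models <- default_flank_hmms()
  set.seed(7)
  its2 <- rand_seq(170)
  seqs <- tibble::tibble(
    sample_id = "s1", species = "Sp",
    bases = paste0("GCATCGATGAAGAACGCAGC", its2, "GCATATCAATAAGCGGAGGA"))
  once <- trim_its2(seqs, models$hmm_58s, models$hmm_28s)
  twice <- trim_its2(once, models$hmm_58s, models$hmm_28s)
  expect_equal(twice$status, "untrimmed-low-score")
  expect_equal(twice$bases, once$bases)
})
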