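#' Run the whole barcode-evaluation chain on a dataset
#'
#' Convenience wrapper composing the pipeline stages: optional flank
#' trimming, progressive alignment, K2P distance matrix, intra/inter
#' partition and divergence summary, Wilcoxon comparison of the two
#' distance sets, barcoding-gap report, leave-one-out identification by
#' both methods, NJ tree (with bootstrap support when requested), species
#' monophyly, haplotype collapse and length/GC statistics.
#'
#' @param seqs A tibble with `sample_id`, `species`, `bases` (e.g. from
#'   [read_fasta()] or [simulate_dataset()]).
#' @param trim Run [trim_its2()] with the default flank models first.
#' @param bootstrap_replicates Bootstrap replicates for the NJ tree; 0
#'   builds the tree without support values.
#' @param seed Seed for the bootstrap (required when
#'   `bootstrap_replicates > 0`).
#' @return An object of class `barcode_evaluation`: a named list with
#'   elements `seqs`, `alignment`, `distances`, `partition`, `summary`,
#'   `wilcoxon`, `gap`, `nearest`, `blast1`, `tree`, `monophyly`,
#'   `haplotypes`, `stats`.
#' @export
run_barcode_evaluation <- function(seqs, trim = FALSE,
                                   bootstrap_replicates = 0, seed = NULL) {
  if (trim) seqs <- trim_its2(seqs)
  aln <- progressive_msa(seqs)
  D <- distance_matrix(aln)
  part <- partition_distances(D, setNames(seqs$species, seqs$sample_id))
  intra <- part$pairs$distance[part$pairs$type == "intraspecific"]
  inter <- part$pairs$distance[part$pairs$type == "interspecific"]
  wil <- if (length(intra) && length(inter))
    wilcoxon_rank_sum(intra[is.finite(intra)], inter[is.finite(inter)])
  else NULL
  tree <- if (bootstrap_replicates > 0) {
    if (is.null(seed)) stop("bootstrap requires a seed", call. = FALSE)
    bootstrap_support(aln, replicates = bootstrap_replicates, seed = seed)
  } else neighbor_joining(D)
  haps <- collapse_haplotypes(seqs)
  structure(list(
    seqs = seqs, alignment = aln, distances = D, partition = part,
    summary = summarize_partition(part), wilcoxon = wil,
    gap = gap_report(part),
    nearest = nearest_distance_identify(D, setNames(seqs$species,
                                                    seqs$sample_id)),
    blast1 = blast1_identify(seqs),
    tree = tree,
    monophyly = monophyly_check(tree, setNames(seqs$species,
                                               seqs$sample_id)),
    haplotypes = haps,
    stats = seq_stats(haps$bases)),
    class = "barcode_evaluation")
}

#' @export
print.barcode_evaluation <- function(x, ...) {
  cat("<barcode_evaluation> ", nrow(x$seqs), " samples, ",
      nrow(x$monophyly), " species\n", sep = "")
  print(x$summary)
  cat(sprintf("interspecific distances < %.3g: %.2f%%\n",
              x$gap$threshold, x$gap$prop_inter_below_pct))
  cat(sprintf("nearest-distance success: %.1f%%; BLAST1 success: %.1f%%\n",
              success_rate(x$nearest), success_rate(x$blast1)))
  cat(sprintf("monophyletic species: %.1f%%\n",
              attr(x$monophyly, "pct_monophyletic")))
  invisible(x)
}
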