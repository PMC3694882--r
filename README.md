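# barcodegap

Evaluation of a DNA barcode for species identification, end to end: does
a short locus (here, the nuclear ribosomal ITS2 spacer) separate
closely related species well enough to identify specimens?

The package implements the standard barcoding-gap evaluation chain used
for medicinal-plant and other single-genus reference libraries:

1. **Flank trimming** — profile-HMM location and excision of the
   conserved 5.8S 3' and 28S 5' flanks, leaving the ITS2 proper
   (`trim_its2()`, with bundled default flank models).
2. **Alignment** — affine-gap Needleman–Wunsch and progressive multiple
   alignment with a UPGMA guide tree (`progressive_msa()`).
3. **Distances** — Kimura 2-parameter distances under pairwise deletion,

   `d = −½ ln[(1 − 2P − Q) √(1 − 2Q)]`,

   partitioned into intra- and interspecific sets with the four standard
   summaries (all inter, minimum inter, all intra, coalescent depth), a
   Wilcoxon rank-sum comparison (exact by enumeration at small n), the
   barcoding-gap histogram on a 0.002 scale, the per-species min-inter
   vs max-intra scatter with the 1:1 line, and the D ratio
   (`distance_matrix()`, `partition_distances()`,
   `summarize_partition()`, `gap_report()`, `wilcoxon_rank_sum()`).
4. **Identification** — leave-one-out species assignment by the
   nearest-distance method and by best local-alignment hit ("BLAST1",
   exact Smith–Waterman with BLASTN-like scoring), with singleton
   exclusion and tie-as-failure rules
   (`nearest_distance_identify()`, `blast1_identify()`,
   `success_rate()`).
5. **Clustering** — neighbor-joining on the K2P matrix, nonparametric
   bootstrap support over column resampling, species-monophyly checks,
   Newick export that masks support below 50%
   (`neighbor_joining()`, `bootstrap_support()`, `monophyly_check()`,
   `write_newick()`).
6. **Haplotypes** — collapse of identical conspecific sequences,
   intraspecific variable-site tables (1-based positions), and
   length/GC summaries (`collapse_haplotypes()`, `variable_sites()`,
   `seq_stats()`).
7. **Simulation** — a K2P sequence simulator that generates study-scale
   datasets (default: 34 species, 103 samples, lengths 145–189 nt, GC
   0.46–0.67, intraspecific depth 0.03, interspecific depth 0.25,
   transition/transversion ratio 2) with full ground truth, so every
   stage above is testable offline (`simulation_config()`,
   `simulate_dataset()`, `mutate_k2p()`).

Functions take tibbles and return tibbles (or classed objects with
`tidy()`/`glance()`/`autoplot()` methods), so stages chain naturally;
trees are `ape::phylo` objects.

## Worked example

Simulate a small six-species dataset with a clean barcoding gap and run
the whole evaluation:

```r
library(barcodegap)

cfg <- simulation_config(n_species = 6, samples_per_species = 3, seed = 2025)
ds  <- simulate_dataset(cfg)
ev  <- run_barcode_evaluation(ds$seqs)
ev
#> <barcode_evaluation> 18 samples, 6 species
#> # A tibble: 4 × 4
#>   measure                 mean     sd     n
#>   <chr>                  <dbl>  <dbl> <int>
#> 1 all_interspecific     0.237  0.0395   135
#> 2 minimum_interspecific 0.181  0.0341     6
#> 3 all_intraspecific     0.0291 0.0120    18
#> 4 coalescent_depth      0.0378 0.0111     6
#> interspecific distances < 0.03: 0.00%
#> nearest-distance success: 100.0%; BLAST1 success: 100.0%
#> monophyletic species: 100.0%
```

Reading the output: conspecific samples sit at K2P distance ≈ 0.03 while
different species are ≈ 0.24 apart and no interspecific distance falls
below 0.03 — a clean gap — so every leave-one-out query is assigned its
true species by both methods and every species forms one branch of the
NJ tree. The pieces are available individually (`ev$gap`, `ev$tree`,
`ev$haplotypes`, ...), e.g.

```r
glance(ev$nearest)
#> # A tibble: 1 × 6
#>   method           n_queries n_evaluated n_singletons n_ambiguous success_rate
#>   <chr>                <int>       <int>        <int>       <int>        <dbl>
#> 1 nearest_distance        18          18            0           0          100

autoplot(ev$gap, type = "histogram")   # intra vs inter distance distributions
autoplot(ev$gap, type = "scatter")     # min-inter vs max-intra, 1:1 line
```

Real data enter through `read_fasta(path, read_sample_table(path))`,
are trimmed with `trim_its2()`, and flow through the same stages.

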