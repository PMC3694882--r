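---
title: "Evaluating an ITS2 barcode: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating an ITS2 barcode: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

DNA barcoding identifies specimens by comparing a short standard locus
against a reference library. For plants whose morphology is uninformative
— spikemosses are a classic case, with dozens of similarly shaped species
growing intermixed — the nuclear ribosomal ITS2 spacer is attractive: it
is short enough for one Sanger read, flanked by the highly conserved 5.8S
and 28S genes (which supply universal primers), and divergent enough
between close relatives to separate species.

Whether a locus *works* as a barcode for a group is an empirical question
with a standard answer sheet: the distribution of within-species versus
between-species distances (the *barcoding gap*), leave-one-out
identification success, and whether conspecific samples cluster together
in a distance tree. `barcodegap` implements that whole evaluation chain —
from raw amplicon to the summary tables — together with a simulator that
generates datasets with known truth, so every stage can be verified
without any external data.

## Pipeline stages and their models

### Flank excision with profile HMMs

The amplicon spans the 3' end of 5.8S, the ITS2 proper, and the 5' start
of 28S. The conserved flanks are located with small profile hidden Markov
models (match/insert/delete architecture) and excised; the ITS2 is
everything strictly between the two matches.

Model training (`build_flank_hmm()`) is maximum likelihood with an
additive pseudocount (default 0.5) on a user-supplied flank alignment;
columns that are mostly gaps (> 50%) are dropped from the match states.
Because the training alignments are tiny, insert and delete transitions
share one global probability (default 0.05) rather than position-specific
values. Decoding (`locate_flank()`) is Viterbi, local in the sequence and
glocal in the profile (every match state is visited or explicitly
deleted), scored in log2 odds against an equal-frequency background — so
unmodelled sequence costs nothing and the reported bit score measures
only the flank match. A record whose flank scores fall below `min_bits`
(default 10 bits, comfortably above what chance matches achieve on
barcode-length sequences) is passed through untrimmed and flagged, never
silently truncated.

The package bundles default models built from small alignments of the
canonical conserved plant motifs around the universal ITS3/ITS4 primer
sites. These bundled alignments are synthetic constructions (the files
are labelled accordingly) — adequate for boundary location and for
testing, but a production annotation should train on curated rRNA flanks
for the taxon at hand.

### Alignment

Pairwise alignment is global Needleman–Wunsch with affine gaps (Gotoh's
three-state recursion); a gap of length $k$ costs
$\text{open} + k\cdot\text{extend}$. Defaults are match $+1$, mismatch
$-1$, open 2, extend 0.5 — mild penalties suited to short, divergent
spacers. `N` is neutral (scores 0 against anything). Tie-breaking is
deterministic: diagonal, then up, then left.

The multiple alignment is classic progressive alignment: pairwise
mismatch-fraction distances, a UPGMA guide tree (ties broken by the
smallest pair of input indices), and leaf-to-root profile–profile
alignment where a column pair is scored by the average of all pairwise
symbol scores. There is no iterative refinement. A consequence worth
knowing: at interspecific divergences of 0.25 and beyond, mild gap
penalties let the aligner open spurious gaps between non-homologous
matches, which inflates distance estimates between distant species. The
simulator therefore exposes its ground-truth alignment (trivially known
when indels are off), and the estimator-recovery checks run on that
truth, isolating the estimator from aligner error.

### K2P distances and the barcoding gap

Distances use the Kimura 2-parameter model. With $P$ and $Q$ the
transition and transversion proportions over compared sites,

$$d = -\tfrac12\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\,\big].$$

Sites are compared under **pairwise deletion**: a column is excluded only
for the pair in which it carries a gap or `N`. This preserves the most
signal for a length-variable spacer; it is recorded in the report rather
than configurable away. When observed divergence saturates the model
($1-2P-Q \le 0$ or $1-2Q \le 0$) the distance is flagged infinite —
excluded from means, propagated to reports, and a hard error only where
an algorithm (NJ) cannot proceed with it. When $Q = 2P$ the formula
reduces exactly to Jukes–Cantor, which the tests exploit as an algebraic
identity.

The partition splits all $n(n-1)/2$ pairs into intra- and interspecific
sets and derives per-species aggregates: the **maximum intraspecific
distance** (species with at least two samples) and the **minimum
interspecific distance** (distance to the nearest heterospecific sample).
Four summaries are reported as mean ± SD (sample SD, $n-1$; a single
value has SD 0): all interspecific, minimum interspecific, all
intraspecific, and the *coalescent depth* (mean over species of the
maximum intraspecific distance) — the standard barcoding definitions
consistent with how such tables are printed. The gap itself is assessed
three ways: overlaid histograms on a fixed 0.002 scale (bins left-closed,
right-open from 0), the per-species scatter of minimum interspecific
against maximum intraspecific distance with the 1:1 line (a point above
the line has a gap; the D ratio min-inter/max-intra is reported as
infinite when a species shows zero intraspecific variation — a gap is
present by definition), and the proportion of interspecific distances
below a small threshold (default 0.03). That proportion is computed over
all pairwise interspecific values.

The two distance sets are compared with a two-sided Wilcoxon rank-sum
test. For combined sizes up to 20 the p-value is exact by enumeration of
all $\binom{n_1+n_2}{n_1}$ rank assignments, with mid-ranks under ties
(the base distribution functions refuse exact p-values with ties, which
distance sets always have); larger samples use the normal approximation
with tie and continuity corrections. The reported statistic is the rank
sum of the first sample.

### Identification

Both classic leave-one-out classifiers are implemented.
**Nearest-distance** assigns each query the species of its
minimum-distance reference; **BLAST1** assigns the species of the
top-scoring local-alignment hit, computed by exact Smith–Waterman with
BLASTN-like scoring ($+2/-3$, gap open 5, extend 2) rather than heuristic
seeded search — at barcode lengths the exact dynamic program costs
nothing and removes seeding nondeterminism. In both methods an exact tie
across species is `"ambiguous"` and counts as a failure, and queries
whose species has no second sample are excluded from the denominator and
listed (a leave-one-out query with no conspecific reference cannot
succeed by definition). The success rate is
$100 \times \text{successes}/\text{evaluated}$; with zero evaluated
queries it is undefined and raising an error is preferred over reporting
a vacuous 100%.

### Trees, bootstrap, monophyly

Neighbor-joining follows Saitou–Nei: minimize
$Q_{ij} = (m-2)d_{ij} - r_i - r_j$, join, apply the two-point branch
formulas, finish with the three-point formula at the final trifurcation.
Ties on $Q$ are broken by the lexicographically smallest pair of cluster
labels (the smallest member tip label of each cluster). A label-based
rule was chosen over an index-based one deliberately: it is equally
deterministic but also independent of input row order, which is what
makes bootstrap supports invariant under leaf permutation — an invariant
the test suite asserts. Negative branch lengths are kept (so additive
matrices are reproduced exactly) and counted in an attribute; `clamp =
TRUE` truncates them to zero, transferring the deficit to a sister edge.

Bootstrap support resamples alignment columns with replacement, rebuilds
the K2P matrix and NJ tree per replicate, and scores each internal edge
by the percentage of replicates containing the same bipartition
(bipartitions, not node identities, so rotation is irrelevant). A
replicate that produces an incomparable pair (no shared sites) or a
saturated distance is redrawn; redraws are counted and capped at ten
times the replicate count. Supports below a threshold (default 50%) are
omitted when writing Newick, the usual convention for published NJ trees.
A species is monophyletic, in the unrooted sense, when some edge
separates exactly its samples from everything else.

### Haplotypes and sequence statistics

Conspecific samples with exactly identical trimmed sequences share a
haplotype, labelled `H1`, `H2`, … in first-seen order. Variable sites are
alignment columns (1-based) where the haplotypes of one species carry at
least two distinct non-gap bases; columns containing `N` are flagged so
ambiguous base calls are not read as substitutions, and sequences
differing only by `N` are conservatively kept as distinct haplotypes.
Published variable-site tables for this marker sometimes use amplicon
rather than trimmed coordinates (positions beyond the trimmed length are
the tell-tale); the reporting here is on whatever alignment is supplied,
so either coordinate system can be obtained by aligning the untrimmed or
the trimmed sequences. GC content counts G+C over A+C+G+T only, and
length/GC summaries follow box-plot conventions (quartiles, median,
mean).

## The simulator: what it emulates and what it does not

`simulate_dataset()` generates datasets with the statistical structure
the analysis assumes, at the scale of a regional single-genus barcoding
study. The defaults are the study conditions, fixed once:

* **34 species, 103 samples**, each species with 1–8 samples. The exact
  per-species breakdown (`study_scale_samples()`) is a fixed profile
  chosen to match that range and total; the true breakdown of any given
  study is immaterial to the statistics evaluated here.
* **Lengths 145–189 nt** drawn uniformly per species; **GC window
  0.46–0.67**, with the root composition at the window midpoint (the
  typical mean GC of this marker) and per-lineage drift providing
  spread. Sequences are rejected and redrawn in the rare event drift
  would leave the configured window, so the range is guaranteed.
* **Interspecific K2P target 0.25** (the minimum interspecific depth
  seen in strongly diverged groups) and **intraspecific target 0.03**,
  expressed as sample-to-sample distances: species ancestors sit on a
  star tree at depth $(d_\text{inter}-d_\text{intra})/2$ and samples
  hang off them at $d_\text{intra}/2$, so both pair classes hit their
  targets in expectation. A star tree is the default because the
  distance summaries, not tree shape, are the simulation target; a
  random-coalescent species tree is available for monophyly exercises.
* **Substitutions** follow the exact K2P transition probabilities at
  the requested distance with transition/transversion rate ratio
  $\kappa$ (default 2), applied per site. Indels are off by default —
  K2P ground truth is exact only without them — and an option introduces
  short deletions to exercise alignment and pairwise deletion.
* Optional conserved flanks (the bundled motif consensuses) exercise the
  trimming stage; trimming a flanked dataset reproduces the unflanked
  one byte-for-byte.

Every draw flows from the single mandatory seed, and regeneration from
the same configuration is bit-identical.

What the simulator does **not** emulate, and hence what passing tests do
not show about real data: rate heterogeneity across sites, recombination
and selection; realistic per-species base-composition differences (all
species descend from one root composition, so GC spread is narrower than
in empirical data); deep phylogenetic structure under the default star
tree; and the empirically common pattern where most species carry zero
intraspecific variation while a few are highly variable — the uniform
intraspecific depth spreads variation evenly, so simulated haplotype
counts are higher than typical published tables. Alignment error on real
length-variable spacers is likewise exercised only via the indel option.

## Numerical choices

Distances are computed in double precision directly from the closed
form; saturation is a flag, not an exception. The Viterbi decoder and
both DP aligners use strictly deterministic tie-breaks (documented
above), so all results are reproducible bit-for-bit given seeds. The
exact Wilcoxon enumeration switches to the normal approximation above a
combined sample size of 20 (184,756 subsets at 10+10 is the practical
ceiling; the two agree within 0.02 there, which the tests assert).
Problem sizes in the test suite were chosen to keep the full suite around
a minute — pairwise brute-force oracles run at sequence lengths ≤ 6 (the
regime where exhaustive enumeration is feasible), estimator recovery uses
10 species × 3 samples across 10 seeds, and the acceptance script runs
the full 34-species/103-sample scale with 1000 bootstrap replicates.

## Known limitations

The progressive aligner has no iterative refinement and will misalign
truly non-homologous regions between distant species, inflating
interspecific distances relative to the substitution truth (the
simulator's exposed true alignment quantifies this). The bundled flank
models are synthetic stand-ins, not curated rRNA profiles. Identification
margins are reported on different scales for the two methods (distance
difference versus score difference) and are not comparable across
methods. The Wilcoxon test treats pairwise distances as independent
observations, as the standard analysis does, although pairs sharing a
sample are correlated — its p-value should be read as descriptive, which
is also why the package reports it without further modelling.
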