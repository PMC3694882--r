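#' Pairwise substitution counts under pairwise deletion
#'
#' Compares two gapped rows of one alignment, excluding every column with a
#' gap or `N` in either row. Transitions are A<->G and C<->T; any other
#' mismatch between proper bases is a transversion.
#'
#' @param row_a,row_b Equal-length gapped strings.
#' @return A list with `L` (compared sites), `P` (transition proportion)
#'   and `Q` (transversion proportion).
#' @export
count_substitutions <- function(row_a, row_b) {
  x <- encode_seq(row_a); y <- encode_seq(row_b)
  if (length(x) != length(y))
    stop("rows must have equal length", call. = FALSE)
  comp <- x < 4L & y < 4L
  L <- sum(comp)
  if (L == 0L)
    stop("no comparable sites: every column has a gap or N in one row",
         call. = FALSE)
  xa <- x[comp]; yb <- y[comp]
  diff <- xa != yb
  ts <- sum(diff & (xa %% 2L) == (yb %% 2L))
  tv <- sum(diff) - ts
  list(L = L, P = ts / L, Q = tv / L)
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, with `P` and `Q` the
#' transition and transversion proportions. When the observed divergence
#' saturates the model (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance is
#' flagged infinite rather than raising an error.
#'
#' @param counts A list with `P` and `Q`, as from [count_substitutions()];
#'   `P`/`Q` may be vectors.
#' @return The K2P distance(s); `Inf` where saturated.
#' @export
k2p_distance <- function(counts) {
  P <- counts$P; Q <- counts$Q
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  # pmax only guards the saturated branch against log(<=0) warnings
  ifelse(w1 <= 0 | w2 <= 0, Inf,
         -0.5 * log(pmax(w1, 1e-300)) - 0.25 * log(pmax(w2, 1e-300)))
}

#' K2P distance matrix of an alignment
#'
#' All pairwise K2P distances under pairwise deletion. Saturated pairs are
#' `Inf` (flagged, matrix still returned); a pair with no comparable sites
#' is a hard error naming the offending ids.
#'
#' @param alignment A tibble from [progressive_msa()] (columns `sample_id`,
#'   `seq`), or a named character vector of equal-length gapped rows.
#' @return A symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
distance_matrix <- function(alignment) {
  if (is.character(alignment)) {
    rows <- alignment
    ids <- names(alignment) %||% paste0("s", seq_along(alignment))
  } else {
    rows <- alignment$seq
    ids <- alignment$sample_id
  }
  n <- length(rows)
  if (n < 2L) stop("need at least two rows", call. = FALSE)
  X <- encode_alignment(rows)
  cnt <- pair_counts_cpp(X)
  L <- cnt$sites
  if (any(L[upper.tri(L)] == 0L)) {
    bad <- which(L == 0L & upper.tri(L), arr.ind = TRUE)[1, ]
    stop("no comparable sites between '", ids[bad[1]], "' and '",
         ids[bad[2]], "'", call. = FALSE)
  }
  Ld <- L; diag(Ld) <- 1L  # avoid 0/0 on the diagonal
  d <- k2p_distance(list(P = cnt$transitions / Ld, Q = cnt$transversions / Ld))
  d <- matrix(d, n, n)
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' Partition pairwise distances into intra- and interspecific sets
#'
#' Every unordered pair is classified exactly once as conspecific or
#' heterospecific. Per-species aggregates: maximum intraspecific distance
#' (species with >= 2 samples; `NA` for singletons) and minimum
#' interspecific distance (the distance to the nearest heterospecific
#' sample; all species).
#'
#' @param matrix Symmetric distance matrix (e.g. [distance_matrix()]).
#' @param species Species label per row, in row order, or a named vector.
#' @return An object of class `distance_partition`: list with `pairs`
#'   (tibble: id1, id2, species1, species2, distance, type) and
#'   `per_species` (tibble: species, n_samples, max_intra, min_inter).
#' @export
partition_distances <- function(matrix, species) {
  ids <- rownames(matrix) %||% paste0("s", seq_len(nrow(matrix)))
  if (!is.null(names(species))) species <- species[ids]
  species <- as.character(species)
  if (length(species) != nrow(matrix) || anyNA(species))
    stop("need a species label for every matrix row", call. = FALSE)
  if (length(unique(species)) < 2L)
    stop("interspecific set undefined: fewer than two species",
         call. = FALSE)
  ut <- which(upper.tri(matrix), arr.ind = TRUE)
  pairs <- tibble::tibble(
    id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
    species1 = species[ut[, 1]], species2 = species[ut[, 2]],
    distance = matrix[ut],
    type = ifelse(species[ut[, 1]] == species[ut[, 2]],
                  "intraspecific", "interspecific"))
  per_species <- purrr::map_dfr(unique(species), function(sp) {
    rows <- which(species == sp)
    intra <- if (length(rows) >= 2L)
      max(matrix[rows, rows][upper.tri(matrix[rows, rows])]) else NA_real_
    inter <- min(matrix[rows, -rows, drop = FALSE])
    tibble::tibble(species = sp, n_samples = length(rows),
                   max_intra = intra, min_inter = inter)
  })
  structure(list(pairs = pairs, per_species = per_species,
                 n = nrow(matrix)),
            class = "distance_partition")
}

#' @export
print.distance_partition <- function(x, ...) {
  cat("<distance_partition> ", x$n, " samples, ",
      nrow(x$per_species), " species; ",
      sum(x$pairs$type == "intraspecific"), " intra / ",
      sum(x$pairs$type == "interspecific"), " inter pairs\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy distance_partition
tidy.distance_partition <- function(x, ...) x$pairs

#' @export
#' @method glance distance_partition
glance.distance_partition <- function(x, ...) {
  s <- summarize_partition(x)
  tidyr::pivot_wider(s[, c("measure", "mean")], names_from = "measure",
                     values_from = "mean")
}

#' Divergence summary (mean +- SD of the four standard measures)
#'
#' The four rows reported in barcoding-gap studies: all interspecific
#' distances; the minimum interspecific distance (mean over species of the
#' distance to the nearest heterospecific sample); all intraspecific
#' distances; and the coalescent depth (mean over species of the maximum
#' intraspecific distance, species with >= 2 samples). SD is the sample
#' (n-1) standard deviation, 0 for a single value. Saturated (infinite)
#' distances are excluded from means and counted in the
#' `n_infinite_excluded` attribute.
#'
#' @param partition A `distance_partition`.
#' @return A tibble with columns `measure`, `mean`, `sd`, `n`.
#' @export
summarize_partition <- function(partition) {
  msd <- function(v) {
    v <- v[!is.na(v)]
    inf <- sum(is.infinite(v))
    v <- v[is.finite(v)]
    list(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0,
         n = length(v), inf = inf)
  }
  sets <- list(
    all_interspecific =
      partition$pairs$distance[partition$pairs$type == "interspecific"],
    minimum_interspecific = partition$per_species$min_inter,
    all_intraspecific =
      partition$pairs$distance[partition$pairs$type == "intraspecific"],
    coalescent_depth = partition$per_species$max_intra)
  rows <- purrr::map(sets, msd)
  out <- tibble::tibble(
    measure = names(rows),
    mean = unname(purrr::map_dbl(rows, "mean")),
    sd = unname(purrr::map_dbl(rows, "sd")),
    n = unname(purrr::map_int(rows, "n")))
  attr(out, "n_infinite_excluded") <- sum(purrr::map_int(rows, "inf"))
  out
}

#' Wilcoxon two-sample rank-sum test
#'
#' Two-sided rank-sum test of the two distance sets. For combined sample
#' sizes up to 20 the p-value is exact, by enumeration of all rank
#' assignments (mid-ranks under ties); otherwise the normal approximation
#' with tie correction and continuity correction is used. The statistic `W`
#' is the rank sum of `x`.
#'
#' @param x,y Non-empty numeric samples.
#' @param method `"auto"` (exact when n1+n2 <= 20), `"exact"`, or
#'   `"normal"`.
#' @return A one-row tibble: `statistic`, `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))             # mid-ranks for ties
  W <- sum(r[seq_len(n1)])
  if (method == "auto") method <- if (N <= 20L) "exact" else "normal"
  if (method == "exact") {
    sets <- combn(N, n1)
    sums <- colSums(matrix(r[sets], nrow = n1))
    p <- 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9))
    p <- min(1, p)
  } else {
    E <- n1 * (N + 1) / 2
    ties <- table(r)
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    V <- n1 * n2 / 12 * ((N + 1) - tiecor)
    z <- (abs(W - E) - 0.5) / sqrt(V)
    z <- max(z, 0)
    p <- min(1, 2 * pnorm(-z))
  }
  tibble::tibble(statistic = W, p_value = p, method = method)
}

#' Barcoding-gap report
#'
#' Histograms of the intra- and interspecific distance distributions on a
#' fixed scale (bins left-closed, right-open, starting at 0), the
#' per-species (max intra, min inter) pairs with the above-1:1-line
#' indicator and the D ratio (min inter / max intra, infinite when the
#' species shows zero intraspecific variation — a gap is present by
#' definition), and the proportion of interspecific distances below a
#' small threshold.
#'
#' @param partition A `distance_partition`.
#' @param bin_width Histogram bin width in distance units (default 0.002).
#' @param threshold Interspecific-overlap threshold (default 0.03).
#' @return An object of class `gap_report`: list with `intra_hist`,
#'   `inter_hist` (tibbles: bin_start, bin_end, count), `species` (tibble:
#'   species, n_samples, max_intra, min_inter, above_line, d_ratio),
#'   `prop_inter_below_pct` and the settings.
#' @export
gap_report <- function(partition, bin_width = 0.002, threshold = 0.03) {
  histo <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v))
      return(tibble::tibble(bin_start = numeric(), bin_end = numeric(),
                            count = integer()))
    nb <- floor(max(v) / bin_width) + 1L
    idx <- pmin(floor(v / bin_width) + 1L, nb)   # left-closed right-open
    cnt <- tabulate(idx, nbins = nb)
    tibble::tibble(bin_start = (seq_len(nb) - 1L) * bin_width,
                   bin_end = seq_len(nb) * bin_width, count = cnt)
  }
  intra <- partition$pairs$distance[partition$pairs$type == "intraspecific"]
  inter <- partition$pairs$distance[partition$pairs$type == "interspecific"]
  sp <- partition$per_species
  max_intra0 <- ifelse(is.na(sp$max_intra), 0, sp$max_intra)
  species <- tibble::tibble(
    species = sp$species, n_samples = sp$n_samples,
    max_intra = max_intra0, min_inter = sp$min_inter,
    above_line = sp$min_inter > max_intra0,
    d_ratio = ifelse(max_intra0 == 0, Inf, sp$min_inter / max_intra0))
  structure(list(
    intra_hist = histo(intra), inter_hist = histo(inter),
    species = species,
    prop_inter_below_pct = 100 * mean(inter < threshold),
    n_intra = length(intra), n_inter = length(inter),
    threshold = threshold, bin_width = bin_width),
    class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report> ", x$n_intra, " intra / ", x$n_inter,
      " inter distances; ",
      sprintf("%.2f%%", x$prop_inter_below_pct),
      " of inter < ", x$threshold, "; ",
      sum(x$species$above_line), "/", nrow(x$species),
      " species above the 1:1 line\n", sep = "")
  invisible(x)
}

#' Plot a barcoding-gap report
#'
#' `type = "histogram"` overlays the intra- and interspecific distance
#' frequency distributions; `type = "scatter"` plots per-species minimum
#' interspecific against maximum intraspecific distance with the 1:1 line
#' (points above the line indicate a gap).
#'
#' @param object A `gap_report`.
#' @param type `"histogram"` or `"scatter"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot gap_report
autoplot.gap_report <- function(object, type = c("histogram", "scatter"),
                                ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    df <- dplyr::bind_rows(
      dplyr::mutate(object$intra_hist, set = "intraspecific"),
      dplyr::mutate(object$inter_hist, set = "interspecific"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start + object$bin_width / 2,
                                     y = .data$count, fill = .data$set)) +
      ggplot2::geom_col(position = "identity", alpha = 0.6,
                        width = object$bin_width) +
      ggplot2::labs(x = "K2P distance", y = "count", fill = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$species,
                    ggplot2::aes(x = .data$max_intra, y = .data$min_inter)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$above_line)) +
      ggplot2::labs(x = "maximum intraspecific distance",
                    y = "minimum interspecific distance",
                    colour = "above 1:1") +
      ggplot2::theme_minimal()
  }
}
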