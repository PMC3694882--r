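# shared leave-one-out assignment given a query x reference "affinity":
# smaller-is-better for distances, larger-is-better for scores
loo_assign <- function(affinity, labels, ids, better = c("min", "max"),
                       method) {
  better <- match.arg(better)
  n <- length(labels)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    refs <- setdiff(seq_len(n), i)
    conspecific <- labels[refs] == labels[i]
    if (!any(conspecific))
      return(tibble::tibble(query_id = ids[i], true_species = labels[i],
                            assigned = NA_character_, success = NA,
                            margin = NA_real_, evaluated = FALSE))
    a <- affinity[i, refs]
    best <- if (better == "min") min(a) else max(a)
    hit <- refs[a == best]
    hit_species <- unique(labels[hit])
    assigned <- if (length(hit_species) == 1L) hit_species else "ambiguous"
    margin <- NA_real_
    if (assigned != "ambiguous") {
      other <- a[labels[refs] != assigned]
      if (length(other))
        margin <- if (better == "min") min(other) - best else best - max(other)
    } else margin <- 0
    tibble::tibble(query_id = ids[i], true_species = labels[i],
                   assigned = assigned,
                   success = identical(assigned, labels[i]),
                   margin = margin, evaluated = TRUE)
  })
  structure(rows, class = c("identification_report", class(rows)),
            method = method,
            singletons = rows$query_id[!rows$evaluated])
}

#' Leave-one-out identification by the nearest-distance method
#'
#' Each sample in turn is treated as a query against all remaining samples.
#' The query is assigned the species of its minimum-distance reference(s);
#' an exact tie across species yields `"ambiguous"`, which counts as a
#' failure. Queries whose species has no other sample (singletons) cannot
#' succeed by definition and are excluded from the evaluated set (and
#' listed in the `singletons` attribute). The margin is the distance to the
#' nearest heterospecific reference minus the best distance.
#'
#' @param matrix Symmetric distance matrix with sample ids as dimnames.
#' @param species Species label per row (row order, or named by id).
#' @return An `identification_report` tibble: `query_id`, `true_species`,
#'   `assigned`, `success`, `margin`, `evaluated`.
#' @export
nearest_distance_identify <- function(matrix, species) {
  ids <- rownames(matrix) %||% paste0("s", seq_len(nrow(matrix)))
  if (!is.null(names(species))) species <- species[ids]
  if (nrow(matrix) < 2L) stop("need at least two samples", call. = FALSE)
  loo_assign(matrix, as.character(species), ids, better = "min",
             method = "nearest_distance")
}

#' Leave-one-out identification by best local-alignment hit (BLAST1-style)
#'
#' The query is assigned the species of its top-scoring Smith–Waterman hit
#' among all remaining samples, under BLASTN-like scoring. For barcode
#' lengths of a couple hundred bases the exact dynamic program is fast, and
#' it removes the nondeterminism of heuristic seeded search. Ties and
#' singletons are handled exactly as in [nearest_distance_identify()]; the
#' margin is the best score minus the best heterospecific score.
#'
#' @param seqs A tibble with `sample_id`, `species` and `bases` columns
#'   (gaps are stripped before alignment).
#' @param match,mismatch,gap_open,gap_extend BLASTN-like scoring defaults:
#'   +2, -3, gap open 5, gap extend 2.
#' @return An `identification_report` tibble.
#' @export
blast1_identify <- function(seqs, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  n <- nrow(seqs)
  if (n < 2L) stop("need at least two records", call. = FALSE)
  codes <- lapply(degap(seqs$bases), encode_seq)
  S <- matrix(0, n, n)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    S[i, j] <- S[j, i] <- sw_score_cpp(codes[[i]], codes[[j]], match,
                                       mismatch, gap_open, gap_extend)
  dimnames(S) <- list(seqs$sample_id, seqs$sample_id)
  loo_assign(S, as.character(seqs$species), seqs$sample_id, better = "max",
             method = "blast1")
}

#' Species-level identification success rate
#'
#' `100 * successes / evaluated`, where evaluated queries are all samples
#' whose species has at least one other sample.
#'
#' @param report An `identification_report`.
#' @return The success rate in percent.
#' @export
success_rate <- function(report) {
  ev <- report$evaluated
  if (!any(ev))
    stop("no evaluated queries (all species are singletons); ",
         "the success rate is undefined", call. = FALSE)
  100 * sum(report$success[ev]) / sum(ev)
}

#' @export
#' @method glance identification_report
glance.identification_report <- function(x, ...) {
  ev <- sum(x$evaluated)
  tibble::tibble(
    method = attr(x, "method"),
    n_queries = nrow(x),
    n_evaluated = ev,
    n_singletons = length(attr(x, "singletons")),
    n_ambiguous = sum(x$assigned == "ambiguous", na.rm = TRUE),
    success_rate = if (ev > 0) 100 * sum(x$success[x$evaluated]) / ev
                   else NA_real_)
}

#' @export
print.identification_report <- function(x, ...) {
  if (!all(c("evaluated", "success") %in% names(x))) return(NextMethod())
  g <- glance(x)
  cat("<identification_report> method: ", g$method, "; ",
      g$n_evaluated, " evaluated (", g$n_singletons, " singletons); ",
      if (is.na(g$success_rate)) "success rate undefined"
      else sprintf("success rate %.1f%%", g$success_rate), "\n", sep = "")
  NextMethod()
}
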