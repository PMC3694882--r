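#' Collapse samples into haplotypes within each species
#'
#' Samples of a species that carry exactly the same (trimmed) sequence
#' share a haplotype. Haplotypes are labelled `H1`, `H2`, ... in
#' first-seen order within each species.
#'
#' @param seqs A tibble with `sample_id`, `species` and `bases` columns.
#' @return An object of class `haplotype_report`: tibble with one row per
#'   haplotype (`species`, `haplotype`, `n_members`, `members`
#'   comma-separated, `bases`).
#' @export
collapse_haplotypes <- function(seqs) {
  out <- seqs |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(function(df, key) {
      hap_idx <- match(df$bases, unique(df$bases))
      df |>
        dplyr::mutate(haplotype = paste0("H", hap_idx)) |>
        dplyr::group_by(.data$haplotype) |>
        dplyr::summarise(
          n_members = dplyr::n(),
          members = paste(.data$sample_id, collapse = ","),
          bases = .data$bases[1], .groups = "drop") |>
        dplyr::arrange(as.integer(sub("^H", "", .data$haplotype)))
    }) |>
    dplyr::ungroup()
  new_bg_tbl(out, class = c("haplotype_report", "tbl_df", "tbl", "data.frame"))
}

#' @export
#' @method glance haplotype_report
glance.haplotype_report <- function(x, ...) {
  per_sp <- dplyr::count(x, .data$species, name = "n_haplotypes")
  tibble::tibble(
    n_species = nrow(per_sp),
    n_haplotypes = nrow(x),
    n_single_haplotype_species = sum(per_sp$n_haplotypes == 1L),
    max_haplotypes = max(per_sp$n_haplotypes))
}

#' Intraspecific variable sites of an aligned set of haplotypes
#'
#' Reports the 1-based positions of alignment columns at which the
#' haplotypes of one species carry at least two distinct non-gap bases,
#' together with the base of each haplotype at each such position. Columns
#' containing `N` are flagged (`has_n`) so ambiguous calls are not
#' mistaken for substitutions.
#'
#' @param haplotypes Equal-length aligned haplotype sequences: a named
#'   character vector, or a tibble with `haplotype` and `seq` columns.
#' @return A tibble in long form: `position`, `haplotype`, `base`,
#'   `has_n`; zero rows when the haplotypes are identical.
#' @export
variable_sites <- function(haplotypes) {
  if (is.data.frame(haplotypes))
    haplotypes <- setNames(haplotypes$seq, haplotypes$haplotype)
  labs <- names(haplotypes) %||% paste0("H", seq_along(haplotypes))
  rows <- do.call(rbind, strsplit(unname(haplotypes), ""))
  var_cols <- which(apply(rows, 2, function(col) {
    u <- unique(col[col != "-"])
    length(u) >= 2L
  }))
  if (!length(var_cols))
    return(tibble::tibble(position = integer(), haplotype = character(),
                          base = character(), has_n = logical()))
  purrr::map_dfr(var_cols, function(j)
    tibble::tibble(position = j, haplotype = labs, base = rows[, j],
                   has_n = any(rows[, j] == "N")))
}

#' Length and GC statistics of haplotype sequences
#'
#' Lengths and GC proportions of degapped sequences, with the five-number
#' summary plus the mean (box-plot conventions: box = interquartile range,
#' line = median). GC counts G+C over A+C+G+T only; `N` is excluded from
#' numerator and denominator.
#'
#' @param seqs A character vector of sequences, or a tibble with a `bases`
#'   column.
#' @return An object of class `seq_stats`: list with `per_seq` (tibble:
#'   length, gc) and `summary` (tibble: metric, min, q25, median, q75,
#'   max, mean).
#' @export
seq_stats <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$bases
  if (!length(seqs)) stop("need at least one sequence", call. = FALSE)
  s <- degap(seqs)
  counts <- function(x, chars) {
    sapply(chars, function(ch)
      nchar(x) - nchar(gsub(ch, "", x, fixed = TRUE)))
  }
  gc_n <- counts(s, "G") + counts(s, "C")
  acgt <- gc_n + counts(s, "A") + counts(s, "T")
  per_seq <- tibble::tibble(length = nchar(s), gc = unname(gc_n / acgt))
  five <- function(v) {
    q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    tibble::tibble(min = q[1], q25 = q[2], median = q[3], q75 = q[4],
                   max = q[5], mean = mean(v))
  }
  summary <- dplyr::bind_rows(
    dplyr::mutate(five(per_seq$length), metric = "length"),
    dplyr::mutate(five(per_seq$gc), metric = "gc")) |>
    dplyr::relocate("metric")
  structure(list(per_seq = per_seq, summary = summary), class = "seq_stats")
}

#' @export
print.seq_stats <- function(x, ...) {
  cat("<seq_stats> ", nrow(x$per_seq), " sequences\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
#' @method tidy seq_stats
tidy.seq_stats <- function(x, ...) x$per_seq

#' @export
#' @method glance seq_stats
glance.seq_stats <- function(x, ...)
  tidyr::pivot_wider(x$summary[, c("metric", "mean")],
                     names_from = "metric", values_from = "mean",
                     names_prefix = "mean_")

#' Box plots of haplotype length and GC content
#'
#' @param object A `seq_stats` object.
#' @param ... Unused.
#' @return A ggplot object with one panel per metric.
#' @export
#' @method autoplot seq_stats
autoplot.seq_stats <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_seq, dplyr::everything(),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
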