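#' Read a sample metadata table
#'
#' Reads the tab-separated sample table that accompanies a barcode FASTA.
#' Required columns are `sample_id` and `species`; `accession` and
#' `locality` are optional and filled with `NA` when absent.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `species`, `accession`,
#'   `locality`.
#' @export
read_sample_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("sample_id", "species") %in% names(tbl)))
    stop("sample table must have columns 'sample_id' and 'species'",
         call. = FALSE)
  if (anyDuplicated(tbl$sample_id))
    stop("duplicate sample_id in sample table: ",
         paste(unique(tbl$sample_id[duplicated(tbl$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (any(is.na(tbl$species) | !nzchar(tbl$species)))
    stop("species labels must be non-empty", call. = FALSE)
  for (col in c("accession", "locality"))
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  tbl[, c("sample_id", "species", "accession", "locality")]
}

#' Read barcode sequences with attached metadata
#'
#' Reads a FASTA file and joins each record to its row of the sample table.
#' The FASTA identifier is the header up to the first whitespace. Bases are
#' uppercased, `U` is mapped to `T`, and any symbol outside `{A,C,G,T,N}`
#' (including IUPAC ambiguity codes) is a hard error: silently degrading
#' distance estimates is worse than failing loudly.
#'
#' @param path Path to a FASTA file.
#' @param sample_table A data frame as returned by [read_sample_table()],
#'   or `NULL` to read sequences without metadata (species set to `NA`).
#' @return A tibble with columns `sample_id`, `species`, `accession`,
#'   `bases`, in file order.
#' @export
read_fasta <- function(path, sample_table = NULL) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  bases <- normalize_bases(as.character(set), id = ids)
  out <- tibble::tibble(sample_id = ids, bases = unname(bases))
  if (is.null(sample_table)) {
    out$species <- NA_character_
    out$accession <- NA_character_
  } else {
    missing <- setdiff(ids, sample_table$sample_id)
    if (length(missing))
      stop("FASTA id(s) absent from sample table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    out <- dplyr::left_join(out, sample_table, by = "sample_id")
  }
  out[, c("sample_id", "species", "accession", "bases")]
}

#' Write sequence records to FASTA
#'
#' @param seqs A tibble with columns `sample_id` and `bases` (gapped rows
#'   allowed via a `seq` column name override).
#' @param path Output path.
#' @param column Name of the column holding the sequence text.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, column = "bases") {
  set <- Biostrings::BStringSet(setNames(seqs[[column]], seqs$sample_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a distance matrix in lower-triangular PHYLIP format
#'
#' The first line holds the number of taxa; each following line holds an
#' identifier and the distances to all previous taxa, printed with six
#' decimals. The matrix must be symmetric (to 1e-9), non-negative, with a
#' zero diagonal.
#'
#' @param matrix A symmetric numeric matrix.
#' @param ids Row identifiers; defaults to `rownames(matrix)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(matrix, ids = rownames(matrix), path) {
  n <- nrow(matrix)
  if (is.null(ids) || length(ids) != n)
    stop("need one id per matrix row", call. = FALSE)
  if (max(abs(matrix - t(matrix))) > 1e-9)
    stop("matrix is not symmetric (tolerance 1e-9)", call. = FALSE)
  if (any(matrix[is.finite(matrix)] < 0))
    stop("negative distances are not allowed", call. = FALSE)
  if (any(abs(diag(matrix)) > 1e-12))
    stop("diagonal must be zero", call. = FALSE)
  lines <- character(n + 1L)
  lines[1] <- format(n)
  for (i in seq_len(n)) {
    row <- if (i == 1L) character(0) else sprintf("%.6f", matrix[i, 1:(i - 1L)])
    lines[i + 1L] <- paste(c(ids[i], row), collapse = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a lower-triangular PHYLIP distance matrix
#'
#' Paired reader for [write_distance_matrix()]; round-trips bit-exactly at
#' six decimals.
#'
#' @param path Path written by [write_distance_matrix()].
#' @return A symmetric numeric matrix with ids as dimnames.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  ids <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    ids[i] <- parts[1]
    if (i > 1L) {
      vals <- as.numeric(parts[-1])
      m[i, 1:(i - 1L)] <- vals
      m[1:(i - 1L), i] <- vals
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Write a tree to Newick, masking weak bootstrap support
#'
#' Internal-node support labels below `min_support` are omitted from the
#' output, the usual convention for published NJ trees (supports under 50%
#' are not shown).
#'
#' @param tree An [ape::phylo] object; node labels, when present, are
#'   bootstrap percentages.
#' @param path Output path.
#' @param min_support Minimum support (percent) for a label to be written.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, min_support = 50) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    keep <- !is.na(sup) & sup >= min_support
    tree$node.label <- ifelse(keep, tree$node.label, "")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
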