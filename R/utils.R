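#' @useDynLib barcodegap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% .data
#' @importFrom stats sd median quantile pnorm setNames
#' @importFrom utils combn head
NULL

BASE_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L, `-` = 5L)

# integer-code a vector of sequence strings (possibly gapped)
encode_seq <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  codes <- BASE_CODES[ch]
  if (anyNA(codes)) {
    bad <- unique(ch[is.na(codes)])
    stop("invalid sequence symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(codes)
}

decode_seq <- function(codes) {
  paste(names(BASE_CODES)[codes + 1L], collapse = "")
}

# rows of equal-length gapped strings -> integer matrix (n x width)
encode_alignment <- function(rows) {
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("alignment rows have unequal widths", call. = FALSE)
  do.call(rbind, lapply(rows, encode_seq))
}

# normalize raw bases: uppercase, U -> T, validate alphabet {A,C,G,T,N}
normalize_bases <- function(x, id = NULL) {
  x <- chartr("u", "t", x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTN]", "", x)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    stop("sequence", if (!is.null(id)) paste0(" '", id[i], "'") else "",
         " contains disallowed symbol(s): ",
         paste(unique(strsplit(bad[i], "")[[1]]), collapse = ", "),
         " (only A, C, G, T, N are accepted)", call. = FALSE)
  }
  if (any(!nzchar(x))) stop("empty sequence not allowed", call. = FALSE)
  x
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

new_bg_tbl <- function(df, class) {
  tibble::new_tibble(df, class = class)
}
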