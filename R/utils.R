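#' @useDynLib famdup, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Reverse complement of a DNA string
#'
#' @param seq A single DNA string over the alphabet A, C, G, T, N (case
#'   insensitive; returned uppercase).
#' @return The reverse complement as a single uppercase string.
#' @examples
#' revcomp("ATGAAATAA")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("acgtnACGTN", "TGCANTGCAN", seq)
  intToUtf8(rev(utf8ToInt(s)))
}

# Fast i.i.d. uniform DNA of length n (uses the current RNG stream).
random_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# Split a string into single characters.
str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

assert_dna <- function(seq, what = "sequence") {
  bad <- setdiff(unique(str_chars(toupper(seq))), DNA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-DNA characters: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
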