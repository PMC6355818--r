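#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on input and returned in file order. Record ids
#' are the first whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase sequences; names are record
#'   ids, in file order.
#' @seealso [write_fasta()]
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wb")  # binary mode: LF line endings everywhere
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Translate a coding sequence with the standard genetic code
#'
#' The terminal stop codon (if present) is removed. Internal stops are kept
#' as `*` and flagged via the `internal_stop` attribute. Any codon containing
#' `N` translates to `X`.
#'
#' @param cds Uppercase DNA string whose length is divisible by 3.
#' @return A single amino-acid string with attribute `internal_stop`
#'   (logical).
#' @examples
#' translate_cds("ATGGATTAA")
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not divisible by 3", call. = FALSE)
  }
  if (n == 0L) {
    out <- ""
    attr(out, "internal_stop") <- FALSE
    return(out)
  }
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N (or other ambiguity)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  out <- paste(aa, collapse = "")
  attr(out, "internal_stop") <- any(aa == "*")
  out
}
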