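#' Built-in dictionary of light- and temperature-responsive cis-elements
#'
#' The promoter-element dictionary used by [scan_promoter()]: named motifs
#' with one or more literal sequence variants, plus the degenerate Sp1 core
#' written `CC(G/A)CCC` (slash-alternatives expand to explicit patterns).
#' Functions follow PlantCARE-style annotations (light response, low
#' temperature response, heat stress, high transcription).
#'
#' @return A data.frame (`name`, `sequence`, `function_`) with one row per
#'   (element, variant) pair.
#' @export
cis_element_table <- function() {
  tab <- rbind(
    c("5' UTR Py-rich stretch", "TTTCTTCTCT",
      "cis-acting element conferring high transcription levels"),
    c("5' UTR Py-rich stretch", "TTTCTCTCTCTCTC",
      "cis-acting element conferring high transcription levels"),
    c("AE-box", "AGAAACAA", "part of a module for light response"),
    c("AT1-motif", "AATTATTTTTTATT", "part of a light-responsive module"),
    c("ATCT-motif", "AATCTGATCG",
      "part of a conserved DNA module involved in light responsiveness"),
    c("Box 4", "ATTAAT",
      "part of a conserved DNA module involved in light responsiveness"),
    c("Box I", "TTTCAAA", "light-responsive element"),
    c("CATT-motif", "GCATTC", "part of a light-responsive element"),
    c("G-box", "CACGTG",
      "cis-acting regulatory element involved in light responsiveness"),
    c("G-box", "CACACATGGAA",
      "cis-acting regulatory element involved in light responsiveness"),
    c("G-box", "CACGTA",
      "cis-acting regulatory element involved in light responsiveness"),
    c("G-box", "TACGTG",
      "cis-acting regulatory element involved in light responsiveness"),
    c("G-box", "CACGAC",
      "cis-acting regulatory element involved in light responsiveness"),
    c("G-box", "GACACGTAGT",
      "cis-acting regulatory element involved in light responsiveness"),
    c("GA-motif", "AAAGATGA", "part of a light-responsive element"),
    c("GAG-motif", "GGAGATG", "part of a light-responsive element"),
    c("GAG-motif", "AGAGAGT", "part of a light-responsive element"),
    c("GATA-motif", "GATAGGG", "part of a light-responsive element"),
    c("GT1-motif", "GGTTAA", "light-responsive element"),
    c("GT1-motif", "AATCCACA", "light-responsive element"),
    c("GTGGC-motif", "GATTCTGTGGC", "part of a light-responsive element"),
    c("Gap-box", "AAATGGAGA", "part of a light-responsive element"),
    c("HSE", "AAAAAATTTC",
      "cis-acting element involved in heat-stress responsiveness"),
    c("HSE", "AGAAAATTCG",
      "cis-acting element involved in heat-stress responsiveness"),
    c("I-box", "GATAGGG", "part of a light-responsive element"),
    c("L-box", "ATCCCACCTAC", "part of a light-responsive element"),
    c("LTR", "CCGAAA",
      "cis-acting element involved in low-temperature responsiveness"),
    c("Sp1", "CC(G/A)CCC", "light-responsive element"),
    c("Sp1", "GGGCGG", "light-responsive element"),
    c("TCT-motif", "TCTTAC", "part of a light-responsive element"),
    c("chs-CMA1a", "TTACTTAA", "part of a light-responsive element"),
    c("rbcS-CMA7a", "GTCGATAAGG", "part of a light-responsive element")
  )
  data.frame(name = tab[, 1L], sequence = tab[, 2L], function_ = tab[, 3L],
             stringsAsFactors = FALSE)
}

# Expand "(X/Y/...)" alternations in a pattern to explicit literal patterns.
expand_pattern <- function(pattern) {
  m <- regexpr("\\(([^)]*)\\)", pattern)
  if (m == -1L) return(pattern)
  inner <- gsub("[()]", "", regmatches(pattern, m))
  alts <- strsplit(inner, "/", fixed = TRUE)[[1L]]
  pre <- substr(pattern, 1L, m - 1L)
  post <- substr(pattern, m + attr(m, "match.length"), nchar(pattern))
  unlist(lapply(alts, function(a) expand_pattern(paste0(pre, a, post))))
}

#' Load a cis-element dictionary
#'
#' @param source A data.frame with columns `name`, `sequence` (literal DNA
#'   or slash-alternation like `CC(G/A)CCC`), `function_`; or a path to a
#'   TSV with those columns; or `NULL` for the built-in table
#'   ([cis_element_table()]).
#' @return A named list of elements; each element is a list with `name`,
#'   `patterns` (expanded literal variants, uppercase), `raw` (as given) and
#'   `function_`.
#' @export
load_element_table <- function(source = NULL) {
  if (is.null(source)) source <- cis_element_table()
  if (is.character(source) && length(source) == 1L) {
    source <- utils::read.delim(source, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(source))
  if (nrow(source) == 0) stop("element table is empty", call. = FALSE)
  need <- c("name", "sequence")
  if (!all(need %in% names(source))) {
    stop("element table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(source))) {
    pats <- toupper(expand_pattern(source$sequence[i]))
    bad <- setdiff(unique(unlist(strsplit(pats, ""))), c("A", "C", "G", "T"))
    if (length(bad) > 0 || any(!nzchar(pats))) {
      stop("malformed pattern in row ", i, " (", source$name[i], "): '",
           source$sequence[i], "'", call. = FALSE)
    }
    nm <- source$name[i]
    if (is.null(out[[nm]])) {
      out[[nm]] <- list(name = nm, patterns = character(0),
                        raw = character(0),
                        function_ = source$function_[i] %||% "")
    }
    out[[nm]]$patterns <- unique(c(out[[nm]]$patterns, pats))
    out[[nm]]$raw <- c(out[[nm]]$raw, source$sequence[i])
  }
  out
}

#' Scan a promoter for cis-element occurrences
#'
#' Reports every occurrence of every element variant (overlaps allowed).
#' With `both_strands = TRUE` (the default, matching how promoter-scan
#' services report elements) the reverse complement of each non-palindromic
#' pattern is also searched; positions are always given on the supplied
#' sequence, 1-based at the leftmost matched base. Each physical site
#' counts once per element: palindromes, and variant pairs that are each
#' other's reverse complement (e.g. Sp1 `CCGCCC`/`GGGCGG`), never
#' double-count an occurrence.
#'
#' @param seq A single DNA promoter sequence.
#' @param elements An element dictionary from [load_element_table()] (or
#'   `NULL` for the built-in table).
#' @param both_strands Also search the minus strand?
#' @return A list with `hits` (data.frame `element`, `pattern`, `position`,
#'   `strand`) and `counts` (named integer vector over all dictionary
#'   elements, zeros included).
#' @export
scan_promoter <- function(seq, elements = NULL, both_strands = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty promoter sequence", call. = FALSE)
  seq <- toupper(seq)
  assert_dna(seq, "promoter")
  if (is.null(elements) || is.data.frame(elements)) {
    elements <- load_element_table(elements)
  }
  find_all <- function(pat) {
    # zero-width lookahead so overlapping occurrences all count
    hit <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1L]]
    if (hit[1L] == -1L) integer(0) else as.integer(hit)
  }
  rows <- list()
  for (el in elements) {
    for (pat in el$patterns) {
      pos <- find_all(pat)
      if (length(pos) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          element = el$name, pattern = pat, position = pos, strand = "+",
          stringsAsFactors = FALSE)
      }
      if (both_strands) {
        rc <- revcomp(pat)
        if (rc != pat) {  # palindromes already counted on the plus strand
          pos <- find_all(rc)
          if (length(pos) > 0) {
            rows[[length(rows) + 1L]] <- data.frame(
              element = el$name, pattern = pat, position = pos, strand = "-",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  hits <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(element = character(0), pattern = character(0),
               position = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  # one count per physical site and element: palindromes and
  # reverse-complementary variant pairs (e.g. Sp1 CCGCCC/GGGCGG) would
  # otherwise count the same occurrence twice
  hits <- hits[order(hits$position, hits$element, hits$strand), , drop = FALSE]
  key <- paste(hits$element, hits$position, nchar(hits$pattern))
  hits <- hits[!duplicated(key), , drop = FALSE]
  rownames(hits) <- NULL
  counts <- vapply(elements, function(el) sum(hits$element == el$name),
                   integer(1L))
  names(counts) <- vapply(elements, `[[`, character(1L), "name")
  list(hits = hits, counts = counts)
}
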