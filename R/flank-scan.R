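#' Scan a 3' flank for a poly(A)-like tail
#'
#' Looks within the first `search_depth_bp` of the gene-strand-oriented 3'
#' flank for either (a) the earliest window of `window_len` bp whose A
#' fraction reaches `min_A_fraction`, or (b) the earliest run of at least
#' `min_run` consecutive `A`s; whichever starts first is reported. The
#' fraction threshold tolerates the base substitutions that erode real
#' retrogene tails.
#'
#' @param flank3 3' flanking sequence, gene-strand oriented (a tail reads as
#'   `A`s, not `T`s).
#' @param search_depth_bp How far into the flank to look (default 300 bp).
#' @param window_len Window length for the fraction test (default 15 bp).
#' @param min_A_fraction Minimum A fraction within the window (default 0.8).
#' @param min_run Minimum length of a pure-A run (default 8 bp).
#' @return A list (`offset_bp` 0-based offset into the flank, `window_len`,
#'   `A_fraction`) or `NULL` when no tail is found. An empty flank returns
#'   `NULL` with a warning.
#' @export
detect_polyA <- function(flank3, search_depth_bp = 300L, window_len = 15L,
                         min_A_fraction = 0.8, min_run = 8L) {
  if (is.na(flank3) || !nzchar(flank3)) {
    warning("empty 3' flank; no poly(A) scan possible")
    return(NULL)
  }
  region <- substr(toupper(flank3), 1L, min(search_depth_bp, nchar(flank3)))
  is_a <- str_chars(region) == "A"
  n <- length(is_a)
  win_start <- NA_integer_; win_frac <- NA_real_
  if (n >= window_len) {
    cs <- cumsum(is_a)
    counts <- cs[window_len:n] - c(0, cs)[seq_len(n - window_len + 1L)]
    ok <- which(counts / window_len >= min_A_fraction)
    if (length(ok) > 0) {
      win_start <- ok[1L]
      win_frac <- counts[win_start] / window_len
    }
  }
  run_start <- NA_integer_; run_len <- NA_integer_
  r <- rle(is_a)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= min_run)
  if (length(hit) > 0) {
    run_start <- ends[hit[1L]] - r$lengths[hit[1L]] + 1L
    run_len <- r$lengths[hit[1L]]
  }
  if (is.na(win_start) && is.na(run_start)) return(NULL)
  if (!is.na(win_start) && (is.na(run_start) || win_start <= run_start)) {
    list(offset_bp = win_start - 1L, window_len = as.integer(window_len),
         A_fraction = win_frac)
  } else {
    list(offset_bp = run_start - 1L, window_len = run_len, A_fraction = 1.0)
  }
}

#' Scan flanks for direct repeats (target-site duplications)
#'
#' Compares the terminal `window5_bp` of the 5' flank against the initial
#' `window3_bp` of the 3' flank (both gene-strand oriented, bracketing a
#' putative retrogene insertion) and reports every maximal shared substring
#' of length at least `min_len` with at most `max_mismatch` substitutions.
#'
#' @param flank5,flank3 Flanking sequences, gene-strand oriented.
#' @param window5_bp,window3_bp Window sizes (default 100 bp each).
#' @param min_len Minimum repeat length (default 8 bp, a typical TSD size).
#' @param max_mismatch Maximum substitutions tolerated (default 1).
#' @return A data.frame (`repeat_seq`, `pos5`, `pos3`, `length`,
#'   `mismatches`) sorted by decreasing length; zero rows when no repeat is
#'   found. Positions are 1-based into the full flanks.
#' @export
detect_direct_repeats <- function(flank5, flank3, window5_bp = 100L,
                                  window3_bp = 100L, min_len = 8L,
                                  max_mismatch = 1L) {
  if (is.na(flank5) || is.na(flank3) || !nzchar(flank5) || !nzchar(flank3)) {
    return(empty_repeat_hits())
  }
  f5 <- toupper(flank5); f3 <- toupper(flank3)
  off5 <- max(0L, nchar(f5) - window5_bp)  # window start offset in flank5
  w5 <- str_chars(substr(f5, off5 + 1L, nchar(f5)))
  w3 <- str_chars(substr(f3, 1L, min(window3_bp, nchar(f3))))
  n5 <- length(w5); n3 <- length(w3)
  hits <- list()
  for (diag in seq.int(-(n5 - 1L), n3 - 1L)) {
    i0 <- max(1L, 1L - diag)          # start in w5
    j0 <- i0 + diag                   # start in w3
    len <- min(n5 - i0, n3 - j0) + 1L
    if (len < min_len) next
    mm <- w5[i0:(i0 + len - 1L)] != w3[j0:(j0 + len - 1L)]
    pref <- c(0L, cumsum(mm))  # pref[k + 1] = mismatches among first k
    r <- 0L
    prev_r <- 0L
    for (l in seq_len(len)) {
      if (r < l - 1L) r <- l - 1L
      while (r < len && pref[r + 2L] - pref[l] <= max_mismatch) r <- r + 1L
      if (r >= l && r > prev_r && r - l + 1L >= min_len) {
        hits[[length(hits) + 1L]] <- data.frame(
          repeat_seq = paste(w5[(i0 + l - 1L):(i0 + r - 1L)], collapse = ""),
          pos5 = off5 + i0 + l - 1L,
          pos3 = j0 + l - 1L,
          length = r - l + 1L,
          mismatches = pref[r + 1L] - pref[l],
          stringsAsFactors = FALSE)
      }
      prev_r <- r
    }
  }
  if (length(hits) == 0) return(empty_repeat_hits())
  out <- do.call(rbind, hits)
  out <- out[order(-out$length, out$mismatches, out$pos5), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_repeat_hits <- function() {
  data.frame(repeat_seq = character(0), pos5 = integer(0), pos3 = integer(0),
             length = integer(0), mismatches = integer(0),
             stringsAsFactors = FALSE)
}
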