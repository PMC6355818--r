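#' Alignment parameters
#'
#' Scoring defaults follow common BLAST practice: BLOSUM62 with gap open -11
#' and gap extend -1 for proteins; match +1 / mismatch -2 with gaps -5, -2
#' for DNA. A gap run of length L costs `gap_open + (L - 1) * gap_extend`.
#' Karlin-Altschul constants default to the published gapped values for
#' these scoring systems and are used by [karlin_evalue()]; they
#' approximate (not reproduce) BLAST's composition-adjusted statistics.
#'
#' @param mode `"local"` (Smith-Waterman style) or `"global"`
#'   (Needleman-Wunsch style).
#' @param alphabet `"protein"` or `"dna"`; selects the default substitution
#'   matrix and Karlin constants.
#' @param substitution_matrix Optional numeric matrix with residue dimnames;
#'   overrides the default.
#' @param gap_open,gap_extend Non-positive gap scores with
#'   `gap_open <= gap_extend <= 0`.
#' @param lambda,K Karlin-Altschul constants (must be positive).
#' @param match,mismatch DNA match/mismatch scores used when building the
#'   default DNA matrix.
#' @return A list of class `align_params`.
#' @export
align_params <- function(mode = c("local", "global"),
                         alphabet = c("protein", "dna"),
                         substitution_matrix = NULL,
                         gap_open = NULL, gap_extend = NULL,
                         lambda = NULL, K = NULL,
                         match = 1, mismatch = -2) {
  mode <- match.arg(mode)
  alphabet <- match.arg(alphabet)
  if (is.null(substitution_matrix)) {
    substitution_matrix <- if (alphabet == "protein") blosum62_matrix()
                           else dna_matrix(match, mismatch)
  }
  if (is.null(gap_open)) gap_open <- if (alphabet == "protein") -11 else -5
  if (is.null(gap_extend)) gap_extend <- if (alphabet == "protein") -1 else -2
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    stop("require gap_open <= gap_extend <= 0", call. = FALSE)
  }
  # published gapped Karlin-Altschul constants matching the default gap
  # scores: BLOSUM62 11/1 and nucleotide +1/-2 with gaps 5/2
  if (is.null(lambda)) lambda <- if (alphabet == "protein") 0.267 else 0.625
  if (is.null(K)) K <- if (alphabet == "protein") 0.041 else 0.41
  structure(list(mode = mode, alphabet = alphabet,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "align_params")
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

dna_matrix <- function(match = 1, mismatch = -2) {
  ab <- DNA_ALPHABET
  S <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(S) <- match
  S["N", ] <- mismatch; S[, "N"] <- mismatch  # N never counts as a match
  S
}

guess_alphabet <- function(seq) {
  ch <- unique(str_chars(toupper(seq)))
  if (all(ch %in% DNA_ALPHABET)) "dna"
  else if (all(ch %in% AA_ALPHABET)) "protein"
  else stop("sequence contains characters outside both alphabets: ",
            paste(setdiff(ch, AA_ALPHABET), collapse = ", "), call. = FALSE)
}

encode_seq <- function(seq, S) {
  codes <- match(str_chars(toupper(seq)), rownames(S))
  if (anyNA(codes)) {
    stop("sequence contains characters absent from the substitution matrix",
         call. = FALSE)
  }
  codes
}

#' Optimal affine-gap pairwise alignment
#'
#' Dynamic-programming alignment (Gotoh) in local or global mode with
#' deterministic traceback: ties are resolved diagonal > up > left.
#'
#' @param a,b Sequences (single strings) over the same alphabet.
#' @param params An [align_params()] object; defaults to local protein
#'   alignment, or local DNA alignment when both inputs look like DNA.
#' @param query_id,subject_id Ids recorded in the result.
#' @return A list of class `alignment_result` with fields `query_id`,
#'   `subject_id`, `score`, `aligned_cols`, `matches`, `mismatches`,
#'   `gap_cols`, `gap_opens`, `identity_pct`, `evalue` (`NA` until
#'   [karlin_evalue()] is applied), and the aligned strings
#'   `a_aln` / `b_aln`.
#' @export
pairwise_align <- function(a, b, params = NULL, query_id = "query",
                           subject_id = "subject") {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  if (is.null(params)) {
    alph_a <- guess_alphabet(a); alph_b <- guess_alphabet(b)
    # a pure-DNA string is also a valid protein string; flag the hard clash
    if (alph_a != alph_b) {
      stop("sequences use different alphabets (", alph_a, " vs ", alph_b, ")",
           call. = FALSE)
    }
    params <- align_params(alphabet = alph_a)
  }
  S <- params$substitution_matrix
  res <- align_pair_cpp(encode_seq(a, S), encode_seq(b, S), S,
                        params$gap_open, params$gap_extend,
                        params$mode == "local")
  ab <- rownames(S)
  decode <- function(codes) {
    paste(ifelse(codes == 0L, "-", ab[pmax(codes, 1L)]), collapse = "")
  }
  a_aln <- decode(res$a_aln); b_aln <- decode(res$b_aln)
  ca <- str_chars(a_aln); cb <- str_chars(b_aln)
  gap <- ca == "-" | cb == "-"
  matches <- sum(!gap & ca == cb)
  mismatches <- sum(!gap & ca != cb)
  gap_cols <- sum(gap)
  runs <- rle(ifelse(ca == "-", "a", ifelse(cb == "-", "b", "m")))
  gap_opens <- sum(runs$values != "m")
  cols <- length(ca)
  structure(list(query_id = query_id, subject_id = subject_id,
                 score = res$score, aligned_cols = cols,
                 matches = matches, mismatches = mismatches,
                 gap_cols = gap_cols, gap_opens = gap_opens,
                 identity_pct = if (cols > 0) 100 * matches / cols else NA_real_,
                 evalue = NA_real_,
                 a_aln = a_aln, b_aln = b_aln,
                 a_start = res$a_start, a_end = res$a_end,
                 b_start = res$b_start, b_end = res$b_end,
                 params = params),
            class = "alignment_result")
}

#' Percent identity of an alignment
#'
#' Identity over alignment length: gap columns are included in the
#' denominator by default (BLAST-style), optionally excluded.
#'
#' @param r An `alignment_result`.
#' @param include_gaps Include gap columns in the denominator?
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(r, include_gaps = TRUE) {
  denom <- if (include_gaps) r$aligned_cols else r$aligned_cols - r$gap_cols
  if (is.null(denom) || denom <= 0) {
    stop("percent identity undefined for an empty alignment", call. = FALSE)
  }
  100 * r$matches / denom
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of distinct
#' ungapped segment pairs with score at least `S` between a query of length
#' `m` and a database of length `n`.
#'
#' @param score Alignment raw score.
#' @param m,n Query and database lengths (residues).
#' @param lambda,K Karlin-Altschul constants (positive).
#' @return The expectation value (non-negative).
#' @examples
#' karlin_evalue(20, 1000, 1000, lambda = 1.33, K = 0.621)
#' @export
karlin_evalue <- function(score, m, n, lambda, K) {
  if (!is.finite(score)) stop("score must be finite", call. = FALSE)
  if (m < 1 || n < 1) stop("m and n must be >= 1", call. = FALSE)
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive", call. = FALSE)
  K * m * n * exp(-lambda * score)
}

#' Harvest family members from a proteome by similarity search
#'
#' Aligns every proteome sequence against the query (local affine-gap
#' alignment, BLOSUM62 by default) and keeps hits passing the expectation
#' value (and optionally raw score) threshold.
#'
#' @param query Named character vector of length 1 (the query protein).
#' @param proteome Named character vector of candidate proteins.
#' @param max_evalue Keep hits with E strictly below this (default the
#'   common genome-screen cutoff 1e-10).
#' @param min_score Optional raw-score floor applied in addition.
#' @param params Alignment parameters (default local protein).
#' @return A data.frame with BLAST tabular style columns `qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `evalue`, `score`, sorted by
#'   descending score; the underlying `alignment_result` objects are in
#'   `attr(, "alignments")`.
#' @export
find_family <- function(query, proteome, max_evalue = 1e-10,
                        min_score = NULL, params = NULL) {
  stopifnot(length(query) == 1L, !is.null(names(query)),
            length(proteome) >= 1L, !is.null(names(proteome)))
  if (is.null(params)) params <- align_params(mode = "local",
                                              alphabet = "protein")
  qid <- names(query)
  nn <- sum(nchar(proteome))
  rows <- vector("list", length(proteome))
  alns <- vector("list", length(proteome))
  for (i in seq_along(proteome)) {
    r <- pairwise_align(query[[1L]], proteome[[i]], params,
                        query_id = qid, subject_id = names(proteome)[i])
    r$evalue <- karlin_evalue(r$score, nchar(query[[1L]]), nn,
                              params$lambda, params$K)
    alns[[i]] <- r
    rows[[i]] <- data.frame(qseqid = qid, sseqid = names(proteome)[i],
                            pident = round(r$identity_pct, 3),
                            length = r$aligned_cols, mismatch = r$mismatches,
                            gapopen = r$gap_opens, evalue = r$evalue,
                            score = r$score, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  keep <- tab$evalue < max_evalue
  if (!is.null(min_score)) keep <- keep & tab$score >= min_score
  tab <- tab[keep, , drop = FALSE]
  alns <- alns[keep]
  ord <- order(-tab$score, tab$sseqid)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "alignments") <- alns[ord]
  tab
}

#' Proportion of differing sites between two aligned proteins
#'
#' Globally aligns the pair and computes the p-distance over ungapped
#' columns (complete deletion of gapped columns).
#'
#' @param a,b Protein sequences.
#' @param params Alignment parameters (default global protein).
#' @return p in `[0, 1]`.
#' @export
p_distance <- function(a, b, params = NULL) {
  if (is.null(params)) params <- align_params(mode = "global",
                                              alphabet = "protein")
  if (params$mode != "global") stop("p_distance requires a global alignment",
                                    call. = FALSE)
  r <- pairwise_align(a, b, params)
  comparable <- r$matches + r$mismatches
  if (comparable == 0) {
    stop("no comparable (ungapped) columns between the sequences",
         call. = FALSE)
  }
  r$mismatches / comparable
}

#' Poisson multiple-hit correction of a p-distance
#'
#' `d = -ln(1 - p)`, the expected substitutions per site under a Poisson
#' model of amino-acid replacement.
#'
#' @param p Proportion of differing sites, `0 <= p < 1`.
#' @return Corrected distance `d >= p`.
#' @examples
#' poisson_correct(0.5)  # log(2)
#' @export
poisson_correct <- function(p) {
  if (any(p < 0)) stop("p must be non-negative", call. = FALSE)
  if (any(p >= 1)) {
    stop("Poisson correction undefined for p >= 1", call. = FALSE)
  }
  -log(1 - p)
}

#' Pairwise Poisson-corrected distance matrix for a protein set
#'
#' @param proteins Named character vector of protein sequences.
#' @param params Alignment parameters (default global protein).
#' @return A symmetric numeric matrix with zero diagonal and the protein
#'   names as dimnames.
#' @export
family_distances <- function(proteins, params = NULL) {
  n <- length(proteins)
  stopifnot(n >= 2L, !is.null(names(proteins)))
  D <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- poisson_correct(p_distance(proteins[[i]], proteins[[j]], params))
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Reference alignment-score enumerator
#'
#' Exhaustively enumerates every alignment path (no dynamic-programming
#' reuse) and returns the optimal score under the same affine-gap convention
#' as [pairwise_align()]. Exponential in sequence length; intended as an
#' independent validation oracle for short sequences only.
#'
#' @param a,b Short sequences (lengths <= ~8 for global, <= ~5 for local).
#' @param params Alignment parameters.
#' @return The optimal alignment score.
#' @export
enumerate_alignment_score <- function(a, b, params) {
  S <- params$substitution_matrix
  ca <- str_chars(toupper(a)); cb <- str_chars(toupper(b))
  go <- params$gap_open; ge <- params$gap_extend
  global_max <- function(xa, xb) {
    n <- length(xa); m <- length(xb)
    rec <- function(i, j, last) {
      if (i > n && j > m) return(0)
      best <- -Inf
      if (i <= n && j <= m) {
        v <- S[xa[i], xb[j]] + rec(i + 1L, j + 1L, "m")
        if (v > best) best <- v
      }
      if (i <= n) {
        v <- (if (last == "x") ge else go) + rec(i + 1L, j, "x")
        if (v > best) best <- v
      }
      if (j <= m) {
        v <- (if (last == "y") ge else go) + rec(i, j + 1L, "y")
        if (v > best) best <- v
      }
      best
    }
    rec(1L, 1L, "")
  }
  if (params$mode == "global") return(global_max(ca, cb))
  # local: best over all substring pairs; terminal gaps only lower the score
  best <- 0
  n <- length(ca); m <- length(cb)
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      v <- global_max(ca[i1:i2], cb[j1:j2])
      if (v > best) best <- v
    }
  }
  best
}
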