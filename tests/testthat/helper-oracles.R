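# Independent oracles used to validate the package's implementations.
# Each is a deliberately naive computation sharing no code path with the
# functions it checks.

# Minimum-loss Dollo reconstruction by exhaustive enumeration over all
# internal-node assignments. The (virtual) ancestor above the root has
# state 1, so a state-0 root costs one stem loss; no 0 -> 1 transition is
# allowed on tree edges.
oracle_dollo_min_losses <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  leaf_st <- as.integer(states[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^nint - 1L)) {
    st <- c(leaf_st, as.integer(intToBits(mask)[seq_len(nint)]))
    ok <- TRUE
    losses <- 0L
    for (k in seq_len(nrow(tree$edge))) {
      p <- st[tree$edge[k, 1L]]; ch <- st[tree$edge[k, 2L]]
      if (p == 0L && ch == 1L) { ok <- FALSE; break }
      if (p == 1L && ch == 0L) losses <- losses + 1L
    }
    if (!ok) next
    if (st[ntip + 1L] == 0L) losses <- losses + 1L  # stem loss
    if (losses < best) best <- losses
  }
  best
}

# Naive position-by-position promoter matcher (vectorised substring
# comparison; no regex machinery). Counts one hit per element and physical
# site, the same site semantics the scanner documents.
oracle_scan_counts <- function(seq, elements, both_strands = TRUE) {
  n <- nchar(seq)
  sites_pat <- function(pat) {
    w <- nchar(pat)
    if (w > n) return(character(0))
    hit <- which(substring(seq, 1:(n - w + 1L), w:n) == pat)
    if (length(hit) == 0) return(character(0))
    paste(hit, w)
  }
  counts <- integer(length(elements))
  names(counts) <- vapply(elements, `[[`, character(1L), "name")
  for (i in seq_along(elements)) {
    sites <- character(0)
    for (pat in elements[[i]]$patterns) {
      sites <- c(sites, sites_pat(pat))
      if (both_strands) {
        rc <- famdup::revcomp(pat)
        if (rc != pat) sites <- c(sites, sites_pat(rc))
      }
    }
    counts[i] <- length(unique(sites))
  }
  counts
}

# Least-squares topology search: fit branch lengths of every unrooted
# topology by ordinary least squares on path-length equations and return
# the topology with the smallest residual. Tractable for n <= 6.
oracle_ls_topology <- function(D) {
  labels <- rownames(D)
  n <- length(labels)
  stopifnot(n <= 6L)
  cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  pairs <- t(combn(labels, 2L))
  dvec <- D[cbind(pairs[, 1L], pairs[, 2L])]
  best <- NULL; best_ss <- Inf
  for (ci in seq_along(cands)) {
    tr <- cands[[ci]]  # [[ restores the compressed tip labels
    ne <- nrow(tr$edge)
    base <- ape::reorder.phylo(tr, "cladewise")
    base$edge.length <- rep(1, ne)
    d1 <- cophenetic(base)[labels, labels]
    A <- matrix(0, nrow(pairs), ne)
    for (k in seq_len(ne)) {
      tk <- base; tk$edge.length[k] <- 2
      dk <- cophenetic(tk)[labels, labels]
      A[, k] <- (dk - d1)[cbind(pairs[, 1L], pairs[, 2L])]
    }
    fit <- stats::lm.fit(A, dvec)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss) { best_ss <- ss; best <- tr }
  }
  best
}

# All k-mers of a string (exact), for verifying shared-substring absence.
oracle_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# Deterministic random sequences for test batteries.
rand_protein <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}
rand_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Write a small FASTA/GFF3 fixture into a temp file, returning the path.
tmp_write <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
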