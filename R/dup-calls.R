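#' Detect tandem clusters from gene order plus tree sisterhood
#'
#' Family genes on one chromosome are chained while consecutive members lie
#' within `max_gap_bp` of each other and are separated by at most
#' `max_intervening_genes` non-family genes; chains of two or more form a
#' cluster. Each cluster's `sisterhood_fraction` is the proportion of
#' members whose sibling subtree in the (rooted) family tree contains
#' another member; clusters at or above `sisterhood_min` are labelled
#' tandem-origin, turning "close phylogenetic relationship at the same
#' chromosomal location" into a testable rule.
#'
#' @param models Gene model table restricted to the family.
#' @param tree Rooted `phylo` tree containing every family gene as a leaf.
#' @param max_gap_bp Maximum gap between consecutive members (default
#'   250 kb).
#' @param max_intervening_genes Maximum non-family genes between consecutive
#'   members (default 5; only enforced when `all_models` is given).
#' @param all_models Optional full gene model table used to count
#'   intervening genes.
#' @param sisterhood_min Threshold for the tandem-origin label (default
#'   0.5).
#' @param ignore_leaves Leaves pruned from the tree before sisterhood is
#'   evaluated, unless they belong to the cluster being scored. Passing the
#'   retro-flagged genes here stops a retrocopy sired by an array member
#'   from displacing that member's true sister: the retrocopy is a
#'   transcriptional export of the array, not a positional neighbour.
#' @return A list of clusters; each is a list with `cluster_id`, `chrom`,
#'   `members` (ordered by coordinate), `sisterhood_fraction`,
#'   `tandem_origin`.
#' @export
detect_tandem_clusters <- function(models, tree, max_gap_bp = 250000L,
                                   max_intervening_genes = 5L,
                                   all_models = NULL,
                                   sisterhood_min = 0.5,
                                   ignore_leaves = NULL) {
  missing <- setdiff(models$gene_id, tree$tip.label)
  if (length(missing) > 0) {
    stop("gene(s) missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  clusters <- list()
  for (ch in sort(unique(models$chrom))) {
    m <- models[models$chrom == ch, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    if (nrow(m) < 2L) next
    brk <- logical(nrow(m) - 1L)
    for (i in seq_len(nrow(m) - 1L)) {
      gap <- m$start[i + 1L] - m$end[i]
      intervening <- 0L
      if (!is.null(all_models)) {
        o <- all_models[all_models$chrom == ch &
                          !(all_models$gene_id %in% models$gene_id), ,
                        drop = FALSE]
        intervening <- sum(o$start > m$end[i] & o$end < m$start[i + 1L])
      }
      brk[i] <- gap > max_gap_bp || intervening > max_intervening_genes
    }
    grp <- cumsum(c(0L, brk))
    for (g in unique(grp)) {
      members <- m$gene_id[grp == g]
      if (length(members) < 2L) next
      drop <- setdiff(ignore_leaves, members)
      stree <- if (length(drop) > 0 &&
                   length(setdiff(tree$tip.label, drop)) >= 2L) {
        ape::keep.tip(tree, setdiff(tree$tip.label, drop))
      } else tree
      sis <- vapply(members, function(gid) {
        any(sibling_leaves(stree, gid) %in% members)
      }, logical(1L))
      frac <- mean(sis)
      clusters[[length(clusters) + 1L]] <- list(
        cluster_id = sprintf("TC%02d", length(clusters) + 1L),
        chrom = ch, members = members, sisterhood_fraction = frac,
        tandem_origin = frac >= sisterhood_min)
    }
  }
  clusters
}

#' Detect segmental duplicate pairs from all-vs-all CDS comparison
#'
#' Aligns every pair of family CDSs (local DNA alignment) and keeps pairs
#' with identity above `min_identity` percent and expectation value below
#' `max_evalue`. Pairs whose two genes sit inside the same tandem-origin
#' cluster are excluded, keeping the tandem and segmental mechanisms
#' disjoint. The `reciprocal_best` flag marks pairs in which each gene is
#' the other's highest-identity partner.
#'
#' @param gene_seqs Named list of `gene_sequences` (needs `$cds`).
#' @param models Gene model table carrying the chromosome of each gene.
#' @param clusters Clusters from [detect_tandem_clusters()] (or `NULL`).
#' @param min_identity Identity threshold in percent, exclusive (default
#'   80).
#' @param max_evalue E-value threshold, exclusive (default 1e-10).
#' @param params DNA alignment parameters (default local, +1/-2, gaps
#'   -5/-2).
#' @return A data.frame (`gene_a`, `gene_b`, `identity_pct`, `evalue`,
#'   `score`, `same_chrom`, `reciprocal_best`), each unordered pair once
#'   with `gene_a < gene_b`.
#' @export
detect_segmental_pairs <- function(gene_seqs, models, clusters = NULL,
                                   min_identity = 80, max_evalue = 1e-10,
                                   params = NULL) {
  ids <- names(gene_seqs)
  stopifnot(length(ids) >= 2L)
  if (is.null(params)) params <- align_params(mode = "local",
                                              alphabet = "dna")
  chrom <- models$chrom[match(ids, models$gene_id)]
  names(chrom) <- ids
  cluster_of <- rep(NA_integer_, length(ids))
  names(cluster_of) <- ids
  if (!is.null(clusters)) {
    for (k in seq_along(clusters)) {
      if (isTRUE(clusters[[k]]$tandem_origin)) {
        cluster_of[clusters[[k]]$members] <- k
      }
    }
  }
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq.int(i + 1L, length(ids))) {
      a <- ids[i]; b <- ids[j]
      if (!is.na(cluster_of[a]) && !is.na(cluster_of[b]) &&
          cluster_of[a] == cluster_of[b]) next
      r <- pairwise_align(gene_seqs[[a]]$cds, gene_seqs[[b]]$cds, params,
                          query_id = a, subject_id = b)
      ev <- karlin_evalue(r$score, nchar(gene_seqs[[a]]$cds),
                         nchar(gene_seqs[[b]]$cds), params$lambda,
                         params$K)
      if (r$aligned_cols > 0 && r$identity_pct > min_identity &&
          ev < max_evalue) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = min(a, b), gene_b = max(a, b),
          identity_pct = r$identity_pct, evalue = ev, score = r$score,
          same_chrom = !is.na(chrom[a]) && !is.na(chrom[b]) &&
            chrom[a] == chrom[b],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity_pct = numeric(0), evalue = numeric(0),
                      score = numeric(0), same_chrom = logical(0),
                      reciprocal_best = logical(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- do.call(rbind, rows)
  best_partner <- function(g) {
    sub <- pairs[pairs$gene_a == g | pairs$gene_b == g, , drop = FALSE]
    if (nrow(sub) == 0) return(NA_character_)
    sub <- sub[order(-sub$identity_pct,
                     ifelse(sub$gene_a == g, sub$gene_b, sub$gene_a)), ,
               drop = FALSE]
    ifelse(sub$gene_a[1L] == g, sub$gene_b[1L], sub$gene_a[1L])
  }
  bests <- vapply(ids, best_partner, character(1L))
  pairs$reciprocal_best <- !is.na(bests[pairs$gene_a]) &
    !is.na(bests[pairs$gene_b]) &
    bests[pairs$gene_a] == pairs$gene_b & bests[pairs$gene_b] == pairs$gene_a
  pairs <- pairs[order(-pairs$identity_pct, pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Export tandem clusters as a BED track
#'
#' Converts each cluster's genomic span from the package's 1-based
#' inclusive coordinates to BED's 0-based half-open convention
#' (`bed_start = start - 1`, `bed_end = end`).
#'
#' @param clusters Output of [detect_tandem_clusters()].
#' @param models Gene model table supplying member coordinates.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(clusters, models, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (cl in clusters) {
    m <- models[models$gene_id %in% cl$members, , drop = FALSE]
    writeLines(paste(cl$chrom, min(m$start) - 1L, max(m$end),
                     cl$cluster_id,
                     sprintf("%d", as.integer(1000 *
                                              cl$sisterhood_fraction)),
                     sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Combine evidence into per-gene duplication calls
#'
#' Evidence flags (tandem-origin cluster membership, segmental partners,
#' retro signature) are recorded independently; the primary mode follows
#' the precedence retro > tandem > segmental > unclassified, reflecting
#' that retroduplication signatures identify older events that later
#' tandem expansion builds upon.
#'
#' @param gene_ids Family gene ids (one call per id).
#' @param clusters Output of [detect_tandem_clusters()].
#' @param pairs Output of [detect_segmental_pairs()].
#' @param retro_genes Ids flagged by [retro_flagged_genes()].
#' @return A data.frame (`gene_id`, `in_tandem_cluster`,
#'   `segmental_partners` comma-joined, `retro_signature`, `primary_mode`).
#' @export
assign_modes <- function(gene_ids, clusters, pairs, retro_genes) {
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  tandem_members <- unlist(lapply(clusters, function(cl) {
    if (isTRUE(cl$tandem_origin)) cl$members else character(0)
  }))
  partners <- function(g) {
    p <- c(pairs$gene_b[pairs$gene_a == g], pairs$gene_a[pairs$gene_b == g])
    paste(sort(p), collapse = ",")
  }
  out <- data.frame(
    gene_id = gene_ids,
    in_tandem_cluster = gene_ids %in% tandem_members,
    segmental_partners = vapply(gene_ids, partners, character(1L)),
    retro_signature = gene_ids %in% retro_genes,
    stringsAsFactors = FALSE)
  out$primary_mode <- ifelse(out$retro_signature, "retro",
                      ifelse(out$in_tandem_cluster, "tandem",
                      ifelse(nzchar(out$segmental_partners), "segmental",
                             "unclassified")))
  rownames(out) <- NULL
  out
}
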