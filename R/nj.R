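#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: at each step the pair `(i, j)`
#' minimising `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is
#' joined, with branch lengths from the usual two-point formulas. Ties in Q
#' are broken lexicographically by the smallest leaf label contained in each
#' node, so the output is deterministic. Negative branch lengths are clamped
#' to zero; the raw values are kept in `attr(, "clamped")`.
#'
#' @param D Symmetric numeric matrix with zero diagonal and unique label
#'   dimnames (e.g. from [family_distances()]).
#' @return An unrooted `phylo` tree (class from \pkg{ape}); for storage the
#'   final three-way join is kept as a basal trifurcation.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa", call. = FALSE)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("distance matrix must have unique labels", call. = FALSE)
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)) ||
      any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  fmt <- function(x) sprintf("%.12g", x)
  newick <- labels       # growing subtree strings
  key <- labels          # smallest contained leaf label, for tie-breaks
  clamped <- list()
  clamp <- function(v, at) {
    if (v < 0) clamped[[length(clamped) + 1L]] <<- c(node = at, raw = v)
    max(v, 0)
  }
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-9 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    kp <- cbind(pmin(key[cand[, 1L]], key[cand[, 2L]]),
                pmax(key[cand[, 1L]], key[cand[, 2L]]))
    pick <- order(kp[, 1L], kp[, 2L])[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    if (key[j] < key[i]) { tmp <- i; i <- j; j <- tmp }  # canonical order
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    vi <- clamp(vi, key[i]); vj <- clamp(vj, key[j])
    nk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- paste0("(", newick[i], ":", fmt(vi), ",",
                     newick[j], ":", fmt(vj), ")")
    mkey <- min(key[i], key[j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], nk[keep]),
                c(nk[keep], 0))
    newick <- c(newick[keep], merged)
    key <- c(key[keep], mkey)
    D <- D2
    n <- n - 1L
  }
  ord <- order(key)  # canonical order of the basal trifurcation
  D <- D[ord, ord]; newick <- newick[ord]; key <- key[ord]
  va <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2, key[1L])
  vb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2, key[2L])
  vc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2, key[3L])
  txt <- paste0("(", newick[1L], ":", fmt(va), ",", newick[2L], ":", fmt(vb),
                ",", newick[3L], ":", fmt(vc), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped") <- clamped
  tree
}

#' Midpoint rooting
#'
#' Roots a tree at the midpoint of the longest leaf-to-leaf path. Pairwise
#' leaf path lengths are unchanged by rooting.
#'
#' @param tree A `phylo` tree with branch lengths (>= 2 leaves).
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("midpoint rooting requires branch lengths", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least two leaves", call. = FALSE)
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; rooting on the first edge")
    return(ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE))
  }
  if (ntip == 2L) {
    h <- sum(tree$edge.length) / 2
    return(ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);",
                                         tree$tip.label[1L], h,
                                         tree$tip.label[2L], h)))
  }
  phangorn::midpoint(tree)
}

#' Leaves of the smallest clade containing a set of anchors
#'
#' @param tree A rooted `phylo` tree.
#' @param anchors Character vector of leaf labels that must all fall inside
#'   the clade.
#' @return Character vector of all leaf labels in the MRCA subtree of the
#'   anchors.
#' @export
clade_with_anchors <- function(tree, anchors) {
  stopifnot(inherits(tree, "phylo"), length(anchors) >= 1L)
  missing <- setdiff(anchors, tree$tip.label)
  if (length(missing) > 0) {
    stop("anchor(s) not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(anchors)) == 1L) return(unique(anchors))
  mrca <- ape::getMRCA(tree, unique(anchors))
  leaves_below(tree, mrca)
}

# Leaf labels below a node (the node itself if it is a tip).
leaves_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  todo <- node
  tips <- integer(0)
  while (length(todo) > 0) {
    ch <- tree$edge[tree$edge[, 1L] %in% todo, 2L]
    tips <- c(tips, ch[ch <= ntip])
    todo <- ch[ch > ntip]
  }
  tree$tip.label[sort(tips)]
}

# Leaf labels in the sibling subtree(s) of a tip, on a rooted tree.
sibling_leaves <- function(tree, tip_label) {
  tip <- match(tip_label, tree$tip.label)
  if (is.na(tip)) stop("tip not in tree: ", tip_label, call. = FALSE)
  parent <- tree$edge[tree$edge[, 2L] == tip, 1L]
  sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], tip)
  unlist(lapply(sibs, leaves_below, tree = tree))
}
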