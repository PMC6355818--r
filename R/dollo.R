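#' Dollo reconstruction of intron presence on a gene tree
#'
#' Reconstructs ancestral intron state (1 = has at least one intron,
#' 0 = intronless) under a Dollo model: introns are ancestral, may be lost
#' on any edge, and are never regained. The root is fixed to state 1 by
#' default (the family ancestor is taken to be intron-bearing); subject to
#' the no-regain constraint, the assignment minimises the number of
#' 1 -> 0 transitions. Each loss edge is a candidate retroduplication
#' event.
#'
#' With the constraint that a state-0 node can have no state-1 descendant,
#' the minimum-loss assignment sets each node to 1 exactly when some leaf
#' below it has state 1, and places one loss on the stem of every maximal
#' all-zero subtree. When every leaf is intronless and the root is forced
#' to 1, the single loss sits on the root's stem, reported with parent
#' `NA`.
#'
#' @param tree A rooted `phylo` tree.
#' @param states Named 0/1 vector covering every leaf exactly once.
#' @param root_state `"force1"` (default) fixes the root to intron-bearing;
#'   `"free"` lets an all-zero tree keep a state-0 root with no losses.
#' @return A list of class `retro_inference`: `node_states` (0/1 per node
#'   number, tips first), `loss_edges` (two-column matrix of parent/child
#'   node numbers; parent `NA` marks a root-stem loss), `n_losses`, and the
#'   input `tree`.
#' @export
dollo_reconstruct <- function(tree, states, root_state = c("force1", "free")) {
  root_state <- match.arg(root_state)
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, names(states))
  if (length(missing) > 0) {
    stop("leaf state missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(states[tips] %in% c(0, 1))) {
    stop("leaf states must be 0 or 1", call. = FALSE)
  }
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  st <- integer(nnode)
  st[seq_len(ntip)] <- as.integer(states[tips])
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    if (st[ch] == 1L) st[p] <- 1L
  }
  stem_loss <- FALSE
  if (root_state == "force1" && st[root] == 0L) {
    st[root] <- 1L
    stem_loss <- TRUE
  }
  loss <- tree$edge[st[tree$edge[, 1L]] == 1L & st[tree$edge[, 2L]] == 0L, ,
                    drop = FALSE]
  if (stem_loss) {
    # the forced-1 root immediately reverts below: a single loss on its stem
    loss <- matrix(c(NA_integer_, root), 1L, 2L)
  }
  colnames(loss) <- c("parent", "child")
  structure(list(node_states = st, loss_edges = loss,
                 n_losses = nrow(loss), tree = tree),
            class = "retro_inference")
}

#' Map intron-loss edges to retroduplication events
#'
#' Each loss edge of a Dollo reconstruction is read as one retroduplication
#' event; every leaf below the edge carries the retro signature.
#'
#' @param inference A `retro_inference` from [dollo_reconstruct()].
#' @return A list with one element per loss edge: `edge` (parent/child node
#'   numbers) and `leaves` (labels of all leaves below the loss).
#' @export
infer_retro_events <- function(inference) {
  stopifnot(inherits(inference, "retro_inference"))
  tree <- inference$tree
  ntip <- length(tree$tip.label)
  lapply(seq_len(nrow(inference$loss_edges)), function(k) {
    child <- inference$loss_edges[k, 2L]
    leaves <- if (is.na(inference$loss_edges[k, 1L]) && child == ntip + 1L) {
      sort(tree$tip.label)  # root-stem loss: every leaf
    } else {
      leaves_below(tree, child)
    }
    list(edge = inference$loss_edges[k, ], leaves = leaves)
  })
}

#' Newick string with retroduplication marks
#'
#' Writes the tree with an `R` label on every internal node whose stem edge
#' carries an inferred intron loss (a retroduplication event). Losses on
#' pendant (single-leaf) edges cannot carry a Newick node label and are
#' reported in the retro table instead.
#'
#' @param inference A `retro_inference` from [dollo_reconstruct()].
#' @return A single Newick string.
#' @export
annotate_retro_tree <- function(inference) {
  stopifnot(inherits(inference, "retro_inference"))
  tree <- inference$tree
  ntip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  kids <- inference$loss_edges[, "child"]
  for (ch in kids[!is.na(kids) & kids > ntip]) {
    labels[ch - ntip] <- "R"
  }
  tree$node.label <- labels
  ape::write.tree(tree)
}

#' Genes flagged as retro-derived by a set of loss events
#' @param events Output of [infer_retro_events()].
#' @return Sorted character vector of flagged leaf labels.
#' @export
retro_flagged_genes <- function(events) {
  sort(unique(unlist(lapply(events, `[[`, "leaves"))))
}
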