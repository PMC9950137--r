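#' Read a rooted Newick tree
#'
#' Wraps \code{ape::read.tree} and validates the result for use with the
#' reconstruction engine: single rooted tree, unique leaf labels, finite
#' non-negative branch lengths on every edge (the root itself needs none).
#' Internal node labels (e.g. named ancestors) are preserved.
#'
#' @param path Path to a Newick file containing one tree.
#' @return An \code{ape::phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1) stop("expected a single tree, found ", length(tree))
    tree <- tree[[1]]
  }
  if (is.null(tree)) stop("could not parse Newick tree in ", path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  # a basal multifurcation (e.g. a star tree) is acceptable: the root is
  # ape's standard node Ntip+1 and reversibility makes its placement moot
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge)) {
    stop("missing branch lengths on non-root edges")
  }
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  invisible(tree)
}

#' Write a tree as Newick
#'
#' @param tree An \code{ape::phylo} object.
#' @param path Output path.
#' @param digits Significant digits for branch lengths.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path, digits = 10) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

# Resolve an internal node by label (or accept a node number); errors on
# leaves and unknown labels.
internal_node_id <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.numeric(node)) {
    id <- as.integer(node)
    if (id < 1 || id > ntip + tree$Nnode) stop("node number out of range")
  } else {
    if (node %in% tree$tip.label) stop("node '", node, "' is a leaf")
    if (is.null(tree$node.label)) stop("tree has no internal node labels")
    hit <- which(tree$node.label == node)
    if (length(hit) != 1) stop("node label not found (or not unique): ", node)
    id <- ntip + hit
  }
  if (id <= ntip) stop("node ", node, " is a leaf; expected an internal node")
  id
}

# Children of each node as a list indexed by node id (ape numbering).
tree_children <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  kids
}

# Edge length leading into each node (NA at the root).
tree_parent_edge <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  len <- rep(NA_real_, n)
  parent <- rep(NA_integer_, n)
  len[tree$edge[, 2]] <- tree$edge.length
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  list(parent = parent, length = len)
}

# Nodes in post-order (children before parents).
postorder_nodes <- function(tree) {
  ord <- ape::reorder.phylo(tree, "postorder")
  unique(c(ord$edge[, 2][!duplicated(ord$edge[, 2])], ape::Ntip(tree) + 1L))
}
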