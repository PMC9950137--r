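# Fitch parsimony on per-column gap presence/absence.
#
# Each column is encoded at the leaves as a binary character (residue or X
# = present, '-' = absent); a bottom-up intersection/union pass and a
# top-down refinement from the root assign a state to every internal node.
# Ties at the target node resolve to "present" by default (configurable).

#' Fitch-parsimony gap mask at an internal node
#'
#' Decides, for every alignment column, whether the ancestor at \code{node}
#' carried a residue (present) or a gap (absent), by Fitch's minimum-change
#' algorithm on the presence/absence character observed at the leaves.
#' \code{X} counts as presence. After the top-down refinement the only
#' remaining two-state set can occur at the root; \code{tie} resolves it.
#'
#' @inheritParams site_log_likelihood
#' @param node Internal node label or number.
#' @param tie State used when present/absence are equally parsimonious at
#'   the refined node: \code{"present"} (default) or \code{"absent"}.
#' @return A \code{gap_mask}: \code{node}, logical \code{present} per
#'   column, \code{n_sites}, and \code{fitch_sets} (diagnostic: the
#'   bottom-up state set at the target node, "P", "A" or "PA").
#' @export
fitch_gap_mask <- function(alignment, tree, node, tie = c("present", "absent")) {
  tie <- match.arg(tie)
  check_leaves(alignment, tree)
  validate_tree(tree)
  vid <- internal_node_id(tree, node)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  n_sites <- alignment$n_sites
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- tree_children(tree)
  pe <- tree_parent_edge(tree)

  # state sets as 2-bit masks: 1 = present, 2 = absent
  sets <- matrix(0L, nnode, n_sites)
  for (i in seq_len(ntip)) {
    gaps <- alignment$matrix[tree$tip.label[i], ] == GAP_CHAR
    sets[i, ] <- ifelse(gaps, 2L, 1L)
  }
  order_parents <- unique(po$edge[, 1])   # postorder: children done first
  for (p in order_parents) {
    ch <- kids[[p]]
    inter <- rep(3L, n_sites)
    uni <- rep(0L, n_sites)
    for (c in ch) {
      inter <- bitwAnd(inter, sets[c, ])
      uni <- bitwOr(uni, sets[c, ])
    }
    sets[p, ] <- ifelse(inter > 0L, inter, uni)
  }

  tie_state <- if (tie == "present") 1L else 2L
  final <- matrix(0L, nnode, n_sites)
  final[root, ] <- ifelse(sets[root, ] == 3L, tie_state, sets[root, ])
  # preorder refinement: keep parent's state when allowed
  pre <- rev(order_parents)
  for (p in pre) {
    for (c in kids[[p]]) {
      if (c <= ntip) next
      s <- sets[c, ]
      keep <- bitwAnd(s, final[p, ]) > 0L
      final[c, ] <- ifelse(keep, final[p, ],
                           ifelse(s == 3L, tie_state, s))
    }
  }

  structure(list(
    node = if (is.character(node)) node else node_label_of(tree, vid),
    present = final[vid, ] == 1L,
    n_sites = n_sites,
    fitch_sets = c("P", "A", "PA")[sets[vid, ]]
  ), class = "gap_mask")
}

#' @export
print.gap_mask <- function(x, ...) {
  cat(sprintf("gap_mask at '%s': %d/%d columns present\n",
              x$node, sum(x$present), x$n_sites))
  invisible(x)
}

check_profile_mask <- function(profile, gap_mask) {
  if (profile$n_sites != gap_mask$n_sites) {
    stop("profile and gap mask cover different numbers of columns")
  }
}

#' Maximum a posteriori ancestor sequence
#'
#' Concatenates the MAP state over the columns called present by the gap
#' mask. MAP ties were already resolved (alphabetically, with a warning)
#' when the profile was built.
#'
#' @param profile An \code{ancestral_profile}.
#' @param gap_mask A \code{gap_mask} for the same node.
#' @return Single ungapped amino-acid string.
#' @export
map_sequence <- function(profile, gap_mask) {
  check_profile_mask(profile, gap_mask)
  if (!any(gap_mask$present)) {
    warning("all columns absent at this node; empty ancestor")
    return("")
  }
  paste(profile$map_state[gap_mask$present], collapse = "")
}

#' Alternative (AltAll) ancestor sequence
#'
#' At every present column: the second-best state where the site is
#' ambiguously reconstructed (second-best posterior probability strictly
#' above the profile's ambiguity threshold, default 0.2), otherwise the MAP
#' state. Never introduces a gap; differs from the MAP sequence exactly at
#' the flagged ambiguous present sites.
#'
#' @inheritParams map_sequence
#' @return Single ungapped amino-acid string.
#' @export
altall_sequence <- function(profile, gap_mask) {
  check_profile_mask(profile, gap_mask)
  if (!any(gap_mask$present)) {
    warning("all columns absent at this node; empty ancestor")
    return("")
  }
  states <- ifelse(profile$ambiguous, profile$alt_state, profile$map_state)
  paste(states[gap_mask$present], collapse = "")
}

#' Mean posterior probability of the MAP states
#'
#' Arithmetic mean of the MAP posterior probability over present columns —
#' the overall reconstruction-confidence summary reported per ancestor.
#'
#' @inheritParams map_sequence
#' @return Numeric in [0, 1].
#' @export
mean_pp <- function(profile, gap_mask) {
  check_profile_mask(profile, gap_mask)
  if (!any(gap_mask$present)) stop("no present columns at this node")
  mean(profile$map_pp[gap_mask$present])
}
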