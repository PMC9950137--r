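# Felsenstein pruning and marginal ancestral reconstruction.
#
# Conditional (inside) likelihoods are computed post-order with per-node,
# per-site scaling factors accumulated in log space; gaps and 'X' contribute
# all-ones vectors (missing data). Marginal posteriors at a node combine
# inside and outside conditional likelihoods per discrete-gamma category,
# with categories weighted by their share of the site likelihood.

# Leaf conditional matrix (20 x n_sites) for one sequence.
leaf_conditionals <- function(states) {
  L <- matrix(0, 20, length(states))
  miss <- is_missing_state(states)
  L[, miss] <- 1
  idx <- aa_index(states[!miss])
  L[cbind(idx, which(!miss))] <- 1
  L
}

# Inside (up) pass for one rate category. Returns per-node 20 x n_sites
# conditionals and per-node log scaling vectors.
up_pass <- function(alignment, tree, model, rate) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  n_sites <- alignment$n_sites
  po <- ape::reorder.phylo(tree, "postorder")
  up <- vector("list", nnode)
  ls <- matrix(0, nnode, n_sites)
  for (i in seq_len(ntip)) {
    up[[i]] <- leaf_conditionals(alignment$matrix[tree$tip.label[i], ])
  }
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2]
    parent <- po$edge[e, 1]
    P <- transition_matrix(model, po$edge.length[e], rate)
    msg <- P %*% up[[child]]
    if (is.null(up[[parent]])) {
      up[[parent]] <- msg
      ls[parent, ] <- ls[child, ]
    } else {
      up[[parent]] <- up[[parent]] * msg
      ls[parent, ] <- ls[parent, ] + ls[child, ]
    }
    # rescale the parent after absorbing each child message
    mx <- apply(up[[parent]], 2, max)
    mx[mx == 0] <- 1
    up[[parent]] <- sweep(up[[parent]], 2, mx, "/")
    ls[parent, ] <- ls[parent, ] + log(mx)
  }
  list(up = up, logscale = ls)
}

check_leaves <- function(alignment, tree) {
  if (!setequal(tree$tip.label, alignment$ids)) {
    stop("tree leaves and alignment ids do not match")
  }
}

# Per-site log-likelihoods for all sites (vector), integrating over the K
# equal-weight gamma categories.
sequence_log_likelihoods <- function(alignment, tree, model) {
  check_leaves(alignment, tree)
  validate_tree(tree)
  root <- length(tree$tip.label) + 1L
  percat <- matrix(NA_real_, model$K, alignment$n_sites)
  for (k in seq_len(model$K)) {
    upk <- up_pass(alignment, tree, model, model$rates[k])
    percat[k, ] <- log(colSums(model$freq * upk$up[[root]])) +
      upk$logscale[root, ]
  }
  apply(percat, 2, log_sum_exp) - log(model$K)
}

#' Site log-likelihood under the pruning algorithm
#'
#' Log of the site likelihood \eqn{\sum_k \frac{1}{K} \sum_x \pi_x
#' L_{root}(x \mid r_k)}, with conditionals computed by post-order pruning,
#' gaps treated as missing data (all-ones conditionals) and per-node scaling
#' against underflow.
#'
#' @param alignment An \code{\link{aa_alignment}} whose ids match the tree
#'   leaves.
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param model A \code{\link{build_model}} result.
#' @param site 1-based alignment column; \code{NULL} returns all sites.
#' @return Log-likelihood (scalar, or vector over sites if
#'   \code{site = NULL}).
#' @export
site_log_likelihood <- function(alignment, tree, model, site = NULL) {
  ll <- sequence_log_likelihoods(alignment, tree, model)
  if (is.null(site)) return(ll)
  if (site < 1 || site > alignment$n_sites) stop("site out of range")
  ll[site]
}

#' Marginal ancestral posteriors at an internal node
#'
#' For each alignment column, the posterior distribution over the 20
#' amino-acid states at the named internal node, marginalizing over all
#' other nodes and the discrete-gamma categories. The default
#' inside-outside implementation combines upward (subtree) and downward
#' (rest-of-tree) conditional likelihoods per category; categories are
#' weighted by their site-likelihood share. \code{method = "reroot"}
#' physically reroots the tree at the node with \code{ape} and reads the
#' root posteriors — the two must agree (reversibility) and the second is
#' retained as an internal cross-check.
#'
#' @inheritParams site_log_likelihood
#' @param node Internal node label (or ape node number).
#' @param ambiguity_threshold Sites whose second-best state has posterior
#'   probability strictly above this are flagged ambiguous (default 0.2).
#' @param method \code{"inside_outside"} (default) or \code{"reroot"}.
#' @return An \code{ancestral_profile}: \code{node}, \code{posterior}
#'   (n_sites x 20), \code{map_state}, \code{map_pp}, \code{alt_state},
#'   \code{alt_pp}, \code{ambiguous}, \code{ambiguity_threshold}.
#' @export
marginal_posteriors <- function(alignment, tree, model, node,
                                ambiguity_threshold = 0.2,
                                method = c("inside_outside", "reroot")) {
  method <- match.arg(method)
  check_leaves(alignment, tree)
  validate_tree(tree)
  vid <- internal_node_id(tree, node)
  post <- switch(method,
    inside_outside = posterior_inside_outside(alignment, tree, model, vid),
    reroot = posterior_reroot(alignment, tree, model, vid))
  label <- if (is.character(node)) node else node_label_of(tree, vid)
  ancestral_profile(label, post, ambiguity_threshold)
}

node_label_of <- function(tree, vid) {
  ntip <- length(tree$tip.label)
  if (!is.null(tree$node.label) && nzchar(tree$node.label[vid - ntip])) {
    tree$node.label[vid - ntip]
  } else {
    paste0("node", vid)
  }
}

posterior_inside_outside <- function(alignment, tree, model, vid) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  n_sites <- alignment$n_sites
  kids <- tree_children(tree)
  pe <- tree_parent_edge(tree)
  # path from root down to vid
  path <- vid
  while (!is.na(pe$parent[path[1]])) path <- c(pe$parent[path[1]], path)
  logpost <- array(NA_real_, c(model$K, 20, n_sites))
  for (k in seq_len(model$K)) {
    upk <- up_pass(alignment, tree, model, model$rates[k])
    # outside pass along the root -> vid path only
    down <- matrix(model$freq, 20, n_sites)
    ls_down <- rep(0, n_sites)
    u <- root
    for (step in seq_along(path)[-1]) {
      v <- path[step]
      sib <- setdiff(kids[[u]], v)
      acc <- down
      for (s in sib) {
        Ps <- transition_matrix(model, pe$length[s], model$rates[k])
        acc <- acc * (Ps %*% upk$up[[s]])
        ls_down <- ls_down + upk$logscale[s, ]
      }
      Pv <- transition_matrix(model, pe$length[v], model$rates[k])
      down <- crossprod(Pv, acc)    # t(P) %*% acc
      mx <- apply(down, 2, max)
      mx[mx == 0] <- 1
      down <- sweep(down, 2, mx, "/")
      ls_down <- ls_down + log(mx)
      u <- v
    }
    num <- upk$up[[vid]] * down
    num[num <= 0] <- .Machine$double.xmin
    logpost[k, , ] <- log(num) +
      rep(upk$logscale[vid, ] + ls_down, each = 20)
  }
  normalize_category_posteriors(logpost)
}

posterior_reroot <- function(alignment, tree, model, vid) {
  ntip <- length(tree$tip.label)
  if (vid == ntip + 1L) {
    return(root_posterior(alignment, tree, model))
  }
  # tag the node, unroot (ids change), then root at the tagged node
  work <- tree
  if (is.null(work$node.label)) work$node.label <- rep("", work$Nnode)
  tag <- "..paleofmo_target.."
  work$node.label[vid - ntip] <- tag
  un <- ape::unroot(work)
  new_vid <- length(un$tip.label) + which(un$node.label == tag)
  rr <- ape::root(un, node = new_vid, resolve.root = FALSE)
  rr$node.label[rr$node.label == tag] <- ""
  root_posterior(alignment, rr, model)
}

root_posterior <- function(alignment, tree, model) {
  root <- length(tree$tip.label) + 1L
  n_sites <- alignment$n_sites
  logpost <- array(NA_real_, c(model$K, 20, n_sites))
  for (k in seq_len(model$K)) {
    upk <- up_pass(alignment, tree, model, model$rates[k])
    num <- model$freq * upk$up[[root]]
    num[num <= 0] <- .Machine$double.xmin
    logpost[k, , ] <- log(num) + rep(upk$logscale[root, ], each = 20)
  }
  normalize_category_posteriors(logpost)
}

# Combine per-category unnormalized log posteriors (K x 20 x n_sites) into a
# n_sites x 20 normalized posterior with equal category priors.
normalize_category_posteriors <- function(logpost) {
  n_sites <- dim(logpost)[3]
  post <- matrix(NA_real_, n_sites, 20, dimnames = list(NULL, AA20))
  for (s in seq_len(n_sites)) {
    lp <- logpost[, , s, drop = FALSE]
    m <- max(lp)
    w <- exp(lp - m)
    px <- apply(w, 2, sum)              # sum over categories
    post[s, ] <- px / sum(px)
  }
  post
}

# Build the profile object from a posterior matrix.
ancestral_profile <- function(node, posterior, ambiguity_threshold = 0.2) {
  stopifnot(ncol(posterior) == 20)
  ord <- t(apply(posterior, 1, order, decreasing = TRUE))
  n <- nrow(posterior)
  map_idx <- ord[, 1]
  alt_idx <- ord[, 2]
  # deterministic tie handling: alphabetically first one-letter code wins
  for (s in seq_len(n)) {
    p <- posterior[s, ]
    tied <- which(p == max(p))
    if (length(tied) > 1) {
      warning(sprintf("MAP tie at column %d; choosing alphabetically first", s))
      tied <- tied[order(AA20[tied])]
      map_idx[s] <- tied[1]
      alt_idx[s] <- tied[2]
    }
  }
  structure(list(
    node = node,
    posterior = posterior,
    map_state = AA20[map_idx],
    map_pp = posterior[cbind(seq_len(n), map_idx)],
    alt_state = AA20[alt_idx],
    alt_pp = posterior[cbind(seq_len(n), alt_idx)],
    ambiguous = posterior[cbind(seq_len(n), alt_idx)] > ambiguity_threshold,
    ambiguity_threshold = ambiguity_threshold,
    n_sites = n
  ), class = "ancestral_profile")
}

#' @export
print.ancestral_profile <- function(x, ...) {
  cat(sprintf("ancestral_profile at '%s': %d columns, %d ambiguous (alt PP > %g)\n",
              x$node, x$n_sites, sum(x$ambiguous), x$ambiguity_threshold))
  invisible(x)
}
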