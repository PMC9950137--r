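# Shared fixtures: tiny trees, random models, and brute-force oracles that
# stay independent of the pruning code they check.

aa_letters <- paleofmo:::AA20

# Rooted 4-leaf tree with exactly two internal nodes:
# ((A:t1,B:t2)u:t5,C:t3,D:t4)root
quartet_tree <- function(t1, t2, t3, t4, t5) {
  txt <- sprintf("((A:%.17g,B:%.17g):%.17g,C:%.17g,D:%.17g):0;",
                 t1, t2, t5, t3, t4)
  tr <- ape::read.tree(text = txt)
  tr$node.label <- c("root", "u")
  tr
}

# Random reversible model: random symmetric exchangeabilities, random
# frequencies, random alpha, K categories.
random_model <- function(K = 2) {
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- stats::runif(190, 0.05, 2)
  S <- S + t(S)
  f <- stats::runif(20, 0.2, 1)
  f <- f / sum(f)
  paleofmo:::model_from_parts(S, f, alpha = stats::runif(1, 0.3, 3), K = K)
}

# One-column alignment over the quartet leaves.
quartet_alignment <- function(states) {
  aa_alignment(c("A", "B", "C", "D"), matrix(states, ncol = 1))
}

# Brute-force site likelihood and marginal posteriors for the quartet tree:
# exhaustive enumeration over both internal-node states and categories.
brute_force_quartet <- function(model, lens, states) {
  ia <- match(states, aa_letters)
  like <- 0
  post_u <- numeric(20)
  post_root <- numeric(20)
  for (k in seq_len(model$K)) {
    P <- lapply(lens, function(t) transition_matrix(model, t, model$rates[k]))
    leafp <- function(P, x, obs) if (is.na(obs)) 1 else P[x, obs]
    for (r in 1:20) for (u in 1:20) {
      w <- (1 / model$K) * model$freq[r] * P[[5]][r, u] *
        leafp(P[[1]], u, ia[1]) * leafp(P[[2]], u, ia[2]) *
        leafp(P[[3]], r, ia[3]) * leafp(P[[4]], r, ia[4])
      like <- like + w
      post_u[u] <- post_u[u] + w
      post_root[r] <- post_root[r] + w
    }
  }
  list(loglik = log(like), post_u = post_u / like,
       post_root = post_root / like)
}

# Balanced 16-leaf tree with equal branch lengths.
balanced_tree <- function(n_leaves = 16, bl = 0.05) {
  tr <- ape::stree(n_leaves, type = "balanced")
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  tr
}

# Hand-made ancestral profile from a matrix of posteriors (rows = sites).
profile_from_posteriors <- function(post, threshold = 0.2) {
  paleofmo:::ancestral_profile("test", post, threshold)
}

# Posterior matrix with one dominant state per site.
simple_posterior <- function(states, pp, alt_states = NULL, alt_pp = NULL) {
  n <- length(states)
  post <- matrix((1 - pp) / 19, n, 20, dimnames = list(NULL, aa_letters))
  if (!is.null(alt_states)) {
    post[] <- rep((1 - pp - alt_pp) / 18, n * 20)
    post[cbind(seq_len(n), match(alt_states, aa_letters))] <- alt_pp
  }
  post[cbind(seq_len(n), match(states, aa_letters))] <- pp
  post / rowSums(post)
}

all_present_mask <- function(n, node = "test") {
  structure(list(node = node, present = rep(TRUE, n), n_sites = n,
                 fitch_sets = rep("P", n)), class = "gap_mask")
}

mask_from_logical <- function(present, node = "test") {
  structure(list(node = node, present = present, n_sites = length(present),
                 fitch_sets = ifelse(present, "P", "A")), class = "gap_mask")
}
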