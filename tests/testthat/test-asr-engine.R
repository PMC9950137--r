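test_that("single-leaf site likelihood equals log pi by stationarity", {
  tr <- ape::read.tree(text = "(A:0.37);")
  m <- build_model("JTT", alpha = 1.114, K = 4)
  aln <- aa_alignment("A", matrix("L", 1, 1))
  expect_equal(site_log_likelihood(aln, tr, m, 1),
               log(unname(m$freq["L"])), tolerance = 1e-12)
})

test_that("pruning likelihood matches exhaustive enumeration on quartets", {
  set.seed(42)
  for (i in 1:10) {
    lens <- runif(5, 0.02, 1.5)
    tr <- quartet_tree(lens[1], lens[2], lens[3], lens[4], lens[5])
    m <- random_model(K = 2)
    states <- sample(aa_letters, 4, replace = TRUE)
    aln <- quartet_alignment(states)
    bf <- brute_force_quartet(m, lens, states)
    expect_equal(site_log_likelihood(aln, tr, m, 1), bf$loglik,
                 tolerance = 1e-10)
  }
})

test_that("all-gap columns carry zero log-likelihood (missing data)", {
  tr <- quartet_tree(0.1, 0.2, 0.3, 0.1, 0.2)
  m <- build_model("JTT", alpha = 1.114, K = 2)
  aln <- quartet_alignment(rep("-", 4))
  expect_equal(site_log_likelihood(aln, tr, m, 1), 0, tolerance = 1e-12)
})

test_that("pruning likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  m <- build_model("JTT", alpha = 1.114, K = 4)
  sim <- simulate_alignment(tr, m, 30, seed = 3)
  mine <- sum(site_log_likelihood(sim$alignment, tr, m))
  pd <- phangorn::phyDat(sim$alignment$matrix, type = "AA")
  ref <- phangorn::pml(tr, pd, model = "JTT", k = 4, shape = 1.114)$logLik
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("marginal posteriors match the exhaustive oracle at both internal nodes", {
  set.seed(7)
  for (i in 1:10) {
    lens <- runif(5, 0.02, 1.5)
    tr <- quartet_tree(lens[1], lens[2], lens[3], lens[4], lens[5])
    m <- random_model(K = 2)
    states <- sample(aa_letters, 4, replace = TRUE)
    aln <- quartet_alignment(states)
    bf <- brute_force_quartet(m, lens, states)
    pu <- marginal_posteriors(aln, tr, m, "u")
    pr <- marginal_posteriors(aln, tr, m, "root")
    expect_equal(unname(pu$posterior[1, ]), unname(bf$post_u),
                 tolerance = 1e-10)
    expect_equal(unname(pr$posterior[1, ]), unname(bf$post_root),
                 tolerance = 1e-10)
  }
})

test_that("two-leaf closed form: posterior at root of a cherry", {
  tr <- ape::read.tree(text = "(A:0.21,B:0.55);")
  tr$node.label <- "root"
  m <- random_model(K = 3)
  aln <- aa_alignment(c("A", "B"), matrix(c("W", "F"), 2, 1))
  prof <- marginal_posteriors(aln, tr, m, "root")
  ia <- match("W", aa_letters); ib <- match("F", aa_letters)
  ref <- numeric(20)
  for (k in seq_len(m$K)) {
    P1 <- transition_matrix(m, 0.21, m$rates[k])
    P2 <- transition_matrix(m, 0.55, m$rates[k])
    ref <- ref + (1 / m$K) * m$freq * P1[, ia] * P2[, ib]
  }
  expect_equal(unname(prof$posterior[1, ]), unname(ref / sum(ref)),
               tolerance = 1e-10)
})

test_that("zero-length star tree with unanimous leaves forces the observed state", {
  tr <- ape::read.tree(text = "(A:0,B:0,C:0,D:0);")
  tr$node.label <- "root"
  m <- build_model("JTT", alpha = 1.114, K = 4)
  aln <- aa_alignment(c("A", "B", "C", "D"), matrix("L", 4, 1))
  prof <- marginal_posteriors(aln, tr, m, "root")
  expect_equal(unname(prof$posterior[1, "L"]), 1, tolerance = 1e-12)
  expect_equal(prof$map_state, "L")
})

test_that("inside-outside and rerooting posteriors agree on synthetic trees", {
  tr <- balanced_tree(16, 0.15)
  m <- build_model("JTT", alpha = 1.114, K = 2)
  sim <- simulate_alignment(tr, m, 20, seed = 5)
  for (nd in c("n3", "n8")) {
    a <- marginal_posteriors(sim$alignment, tr, m, nd)
    b <- marginal_posteriors(sim$alignment, tr, m, nd, method = "reroot")
    expect_equal(a$posterior, b$posterior, tolerance = 1e-8)
    expect_lt(max(abs(rowSums(a$posterior) - 1)), 1e-8)
  }
})

test_that("posterior errors are informative", {
  tr <- quartet_tree(0.1, 0.2, 0.3, 0.1, 0.2)
  m <- build_model("JTT", alpha = 1.114, K = 2)
  aln <- quartet_alignment(c("A", "C", "D", "E"))
  expect_error(marginal_posteriors(aln, tr, m, "A"), "leaf")
  expect_error(marginal_posteriors(aln, tr, m, "nope"), "not found")
  aln2 <- aa_alignment(c("A", "B", "C", "E"),
                       matrix(c("A", "C", "D", "E"), 4, 1))
  expect_error(marginal_posteriors(aln2, tr, m, "u"), "do not match")
})
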