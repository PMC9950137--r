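make_record <- function(parent_pp, child_pp, parent_alt_pp = 0.1,
                        child_alt_pp = 0.1, parent_state = "D",
                        child_state = "N", parent_alt = "E",
                        child_alt = "Q") {
  data.frame(column = 1L, position = 1L,
             parent_state = parent_state, parent_pp = parent_pp,
             parent_alt = parent_alt, parent_alt_pp = parent_alt_pp,
             child_state = child_state, child_pp = child_pp,
             child_alt = child_alt, child_alt_pp = child_alt_pp,
             stringsAsFactors = FALSE)
}

test_that("substitutions are enumerated where MAP states differ", {
  parent <- profile_from_posteriors(simple_posterior(c("A", "C", "D"), 0.95))
  child <- profile_from_posteriors(simple_posterior(c("A", "C", "E"), 0.95))
  mask <- all_present_mask(3)
  recs <- enumerate_substitutions(parent, child, mask, mask)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$position, 3L)
  expect_equal(recs$parent_state, "D")
  expect_equal(recs$child_state, "E")

  none <- enumerate_substitutions(parent, parent, mask, mask)
  expect_equal(nrow(none), 0)
})

test_that("positions use descendant numbering across child gap columns", {
  parent <- profile_from_posteriors(simple_posterior(c("A", "C", "D"), 0.95))
  child <- profile_from_posteriors(simple_posterior(c("A", "C", "E"), 0.95))
  child_mask <- mask_from_logical(c(FALSE, TRUE, TRUE))
  recs <- enumerate_substitutions(parent, child, all_present_mask(3),
                                  child_mask)
  expect_equal(recs$column, 3L)
  expect_equal(recs$position, 2L)   # first child-present column is residue 1
})

test_that("PP classification follows the two-node rules", {
  expect_equal(classify_by_pp(make_record(0.95, 0.90)), "true_substitution")
  # weak parent whose credible alternative differs from the child MAP
  expect_equal(classify_by_pp(make_record(0.65, 0.92, parent_alt_pp = 0.30,
                                          parent_alt = "E",
                                          child_state = "N")),
               "ambiguous_included")
  # weak parent whose alternative IS the child MAP: likely artifactual
  expect_equal(classify_by_pp(make_record(0.65, 0.92, parent_alt_pp = 0.30,
                                          parent_alt = "N",
                                          child_state = "N")),
               "excluded")
  # threshold equalities are strict: exactly 0.8/0.8 is excluded
  expect_equal(classify_by_pp(make_record(0.8, 0.8)), "excluded")
})

test_that("PP classification matches an independent rule oracle on random profiles", {
  # literal restatement of the selection rules, written against the text,
  # kept separate from the implementation
  oracle <- function(r) {
    if (r$parent_pp > 0.8 && r$child_pp > 0.8) return("true_substitution")
    ok_parent <- r$parent_pp < 0.8 && r$parent_alt_pp > 0.2 &&
      r$parent_alt != r$child_state
    ok_child <- r$child_pp < 0.8 && r$child_alt_pp > 0.2 &&
      r$child_alt != r$parent_state
    if (ok_parent || ok_child) return("ambiguous_included")
    "excluded"
  }
  set.seed(99)
  n <- 2000
  for (i in seq_len(n)) {
    r <- make_record(runif(1, 0.4, 1), runif(1, 0.4, 1),
                     parent_alt_pp = runif(1, 0, 0.5),
                     child_alt_pp = runif(1, 0, 0.5),
                     parent_alt = sample(c("E", "N", "Q"), 1),
                     child_alt = sample(c("D", "E", "Q"), 1))
    expect_identical(classify_by_pp(r), oracle(r))
  }
})

test_that("conservation profiles report modal frequency and entropy", {
  ids <- paste0("s", 1:10)
  col1 <- rep("H", 10)
  col2 <- c(rep("H", 8), rep("N", 2))
  col3 <- c(aa_letters[1:10])
  col4 <- rep("-", 10)
  aln <- aa_alignment(ids, cbind(col1, col2, col3, col4))
  cp <- conservation_profile(aln, ids)
  expect_equal(cp$modal_freq[1], 1)
  expect_equal(cp$entropy[1], 0)
  expect_true(cp$conserved[1])
  # 8/10 sits exactly on the default (inclusive) threshold
  expect_equal(cp$modal_freq[2], 0.8)
  expect_true(cp$conserved[2])
  # 10 distinct states: entropy log2(10); uniform over 20 would be log2(20)
  expect_equal(cp$entropy[3], log2(10), tolerance = 1e-12)
  expect_false(cp$conserved[3])
  # all-gap column undefined and not conserved
  expect_false(cp$conserved[4])
  expect_true(is.na(cp$modal_freq[4]))
  expect_error(conservation_profile(aln, character(0)), "empty clade")
})

test_that("maximum-entropy column reaches log2(20) bits", {
  ids <- paste0("s", 1:20)
  aln <- aa_alignment(ids, matrix(aa_letters, 20, 1))
  cp <- conservation_profile(aln, ids)
  expect_equal(cp$entropy[1], log2(20), tolerance = 1e-12)
})

funnel_fixture <- function() {
  # 10 records: 4 true, 3 ambiguous-included, 3 excluded
  recs <- rbind(
    make_record(0.95, 0.9), make_record(0.99, 0.85),
    make_record(0.81, 0.81), make_record(0.9, 0.95),
    make_record(0.65, 0.92, parent_alt_pp = 0.3, parent_alt = "E"),
    make_record(0.92, 0.6, child_alt_pp = 0.35, child_alt = "Q"),
    make_record(0.7, 0.9, parent_alt_pp = 0.25, parent_alt = "H"),
    make_record(0.65, 0.92, parent_alt_pp = 0.3, parent_alt = "N"),
    make_record(0.5, 0.5), make_record(0.79, 0.9)
  )
  recs$column <- 1:10
  recs$position <- 1:10
  recs
}

test_that("the funnel filters by stage and logs drops", {
  recs <- funnel_fixture()
  ids <- paste0("s", 1:6)
  aln <- aa_alignment(ids, matrix("H", 6, 10))
  cons <- conservation_profile(aln, ids)          # everything conserved
  ann <- data.frame(position = 1:10,
                    category = c("active_site", "tunnel", "other", "other",
                                 "FAD_proximal", "NADPH_shell1", "other",
                                 "active_site", "tunnel", "other"),
                    location = c("core", "core", "surface", "core",
                                 "surface", "core", "surface", "core",
                                 "core", "surface"),
                    domain = "FAD_binding", stringsAsFactors = FALSE)
  out <- apply_funnel(recs, cons, cons, cons, ann)
  expect_equal(unname(out$counts["listed"]), 10)
  expect_equal(unname(out$counts["pp_filtered"]), 7)
  # stage 3 drops the surface+other records among the 7 survivors (cols 3, 7)
  expect_equal(unname(out$counts["structural"]), 5)
  expect_true(all(out$dropped$drop_stage[out$dropped$column %in% c(8, 9, 10)]
                  == "pp_filter"))
  expect_true(all(out$dropped$drop_stage[out$dropped$column %in% c(3, 7)]
                  == "structural"))
  # survivors never include records dropped at stage 1
  expect_false(any(out$records$pp_class == "excluded"))
})

test_that("conservation stage drops unconserved columns before structure", {
  recs <- funnel_fixture()[1:4, ]
  ids <- paste0("s", 1:6)
  aln_var <- aa_alignment(ids, matrix(sample(aa_letters[1:6]), 6, 10))
  cons_none <- conservation_profile(aln_var, ids)  # nothing conserved
  ann <- data.frame(position = 1:10, category = "active_site",
                    location = "core", domain = "FAD_binding",
                    stringsAsFactors = FALSE)
  out <- apply_funnel(recs, cons_none, cons_none, cons_none, ann)
  expect_equal(unname(out$counts["conserved"]), 0)
  expect_true(all(out$dropped$drop_stage == "conservation"))
})

test_that("funnel labels lineage-specific conservation", {
  ids <- paste0("s", 1:8)
  sn <- ids[1:4]; bv <- ids[5:8]
  mat <- cbind(c(rep("H", 4), rep("A", 1), rep("C", 1), rep("D", 1), "E"))
  aln <- aa_alignment(ids, mat)
  lab <- paleofmo:::conservation_label(1,
    conservation_profile(aln, ids),
    conservation_profile(aln, sn),
    conservation_profile(aln, bv))
  expect_equal(lab, "conserved_SN_lineage")
})

test_that("mutant sets nest and explicit subsets are validated", {
  recs <- data.frame(
    position = c(60, 100, 222, 275, 300, 310, 426, 500),
    category = c("active_site", "active_site", "tunnel", "NADPH_shell1",
                 "FAD_proximal", "NADPH_shell2", "NADPH_shell1", "other"),
    stringsAsFactors = FALSE)
  sets <- compose_mutant_sets(recs,
                              extra_sets = list("3x" = c(60, 275, 426)))
  expect_equal(sets[["4x"]], c(60, 100))
  expect_true(all(sets[["4x"]] %in% sets[["12x"]]))
  expect_true(all(sets[["12x"]] %in% sets[["16x"]]))
  expect_equal(length(sets[["16x"]]), 8)
  expect_equal(sets[["3x"]], c(60, 275, 426))
  expect_error(compose_mutant_sets(recs, extra_sets = list(bad = c(60, 999))),
               "999")
})

test_that("the funnel is idempotent and order-independent within a stage", {
  recs <- funnel_fixture()
  ids <- paste0("s", 1:6)
  aln <- aa_alignment(ids, matrix("H", 6, 10))
  cons <- conservation_profile(aln, ids)
  ann <- data.frame(position = 1:10, category = "active_site",
                    location = "core", domain = "FAD_binding",
                    stringsAsFactors = FALSE)
  out1 <- apply_funnel(recs, cons, cons, cons, ann)
  shuffled <- recs[sample(nrow(recs)), ]
  out2 <- apply_funnel(shuffled, cons, cons, cons, ann)
  expect_setequal(out1$records$column, out2$records$column)
  out3 <- apply_funnel(out1$records[names(recs)], cons, cons, cons, ann)
  expect_equal(nrow(out3$records), nrow(out1$records))
})
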