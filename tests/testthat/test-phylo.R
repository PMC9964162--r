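test_that("p-distances count mismatches over comparable columns", {
  m <- msa(c("a", "b", "c"), c("AAAA", "AAAT", "AAAA"))
  d <- p_distance_matrix(m)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
})

test_that("p-distances skip gaps and X, and error with nothing comparable", {
  # hand count: comparable columns a/b = 1,2,5 (col3 gap in b, col4 X in a)
  # mismatches at col 5 only -> 1/3
  m <- msa(c("a", "b", "c"),
           c("ACDXA",
             "AC-GT",
             "AAAAA"))
  d <- p_distance_matrix(m)
  expect_equal(d["a", "b"], 1 / 3)

  m2 <- msa(c("a", "b", "c"), c("A--A", "-AA-", "AAAA"))
  expect_error(p_distance_matrix(m2), "zero comparable")
})

test_that("three taxa resolve with closed-form branch lengths", {
  dm <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.4,
                 0.5, 0.4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  # branch to a = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.2, 0.1, 0.3),
               tolerance = 1e-12)
})

test_that("nj_tree rejects bad input and clamps negative lengths", {
  dm <- matrix(c(0, 1, 1, 2, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(dm), "non-symmetric")
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("NJ recovers random additive matrices exactly", {
  set.seed(606)
  for (rep in 1:15) {
    cs <- random_additive_case(sample(4:8, 1))
    tr <- nj_tree(cs$dm)
    # recovered path-length matrix equals the input additive matrix
    got <- cophenetic(tr)[rownames(cs$dm), colnames(cs$dm)]
    expect_equal(got, cs$dm, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(tr), cs$tree)[[1L]], 0)
  }
})

test_that("taxon order does not change the tree (up to isomorphism)", {
  set.seed(33)
  cs <- random_additive_case(6)
  tr1 <- nj_tree(cs$dm)
  perm <- sample(6)
  tr2 <- nj_tree(cs$dm[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2)[[1L]], 0)
  expect_equal(cophenetic(tr2)[rownames(cs$dm), rownames(cs$dm)],
               cophenetic(tr1), tolerance = 1e-8)
})

two_block_msa <- function() {
  # two clearly distinct blocks of near-identical sequences
  b1 <- "ACDEFGHIKLMNPQRSTVWY"
  b2 <- "YWVTSRQPNMLKIHGFEDCA"
  tweak <- function(s, i, ch) { substr(s, i, i) <- ch; s }
  msa(c("a1", "a2", "a3", "b1", "b2", "b3"),
      c(b1, tweak(b1, 3, "A"), tweak(b1, 7, "A"),
        b2, tweak(b2, 4, "C"), tweak(b2, 9, "C")))
}

test_that("bootstrap support is deterministic, bounded and saturates", {
  m <- two_block_msa()
  tr1 <- bootstrap_support(m, n_reps = 50, seed = 99)
  tr2 <- bootstrap_support(m, n_reps = 50, seed = 99)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  supp <- attr(tr1, "supports")
  expect_true(all(supp >= 0 & supp <= 100))
  # the a|b split exists and is certain
  pp <- ape::prop.part(tr1)
  a_idx <- sort(match(c("a1", "a2", "a3"), tr1$tip.label))
  split_node <- which(vapply(pp, function(part)
    identical(sort(part), a_idx) ||
      identical(sort(setdiff(seq_len(6), part)), a_idx), TRUE))
  expect_length(split_node, 1L)
  expect_equal(as.numeric(tr1$node.label[[split_node]]), 100)
})

test_that("bootstrap supports vary within binomial noise across seeds", {
  set.seed(314)
  fam <- generate_family(sim_params(n_per_group = c(plant = 12),
                                    decoy_fraction = 0, seed = 2718))
  m <- fam$msa
  t1 <- bootstrap_support(m, n_reps = 400, seed = 1)
  t2 <- bootstrap_support(m, n_reps = 400, seed = 2)
  s1 <- attr(t1, "supports"); s2 <- attr(t2, "supports")
  # binomial sd at n = 400 is <= 2.5 points; allow 5 sd
  expect_true(all(abs(s1 - s2) <= 13))
})

test_that("clade congruence reports planted composition and exceptions", {
  # rooted shape: outgroup og, clade (q1,q2,q3), others (e1,e2)
  tr <- ape::read.tree(text = "((((q1:1,q2:1):1,q3:1):1,(e1:1,e2:1):1):1,og:1);")
  calls <- data.frame(
    seq_id = c("q1", "q2", "q3", "e1", "e2", "og"),
    status = c("substituted_Q", "substituted_Q", "substituted_Q",
               "canonical_E", "canonical_E", "canonical_E"),
    stringsAsFactors = FALSE)
  cg <- clade_catalysis_congruence(tr, calls, clade_seed_taxa = c("q1", "q3"),
                                   outgroup = "og")
  expect_setequal(cg$clade_members, c("q1", "q2", "q3"))
  expect_equal(unname(cg$inside_fraction[["substituted_Q"]]), 1.0)
  expect_false("substituted_Q" %in% names(cg$outside_fraction))
  expect_equal(nrow(cg$exceptions), 0L)

  # one exception inside
  calls2 <- calls; calls2$status[calls2$seq_id == "q2"] <- "canonical_E"
  cg2 <- clade_catalysis_congruence(tr, calls2, c("q1", "q3"), "og")
  expect_equal(unname(cg2$inside_fraction[["substituted_Q"]]), 2 / 3)
  expect_equal(cg2$exceptions$seq_id, "q2")
  expect_equal(cg2$exceptions$where, "inside")

  expect_error(clade_catalysis_congruence(tr, calls, character(), "og"),
               "empty clade seed")
  expect_error(clade_catalysis_congruence(tr, calls, "zz", "og"),
               "absent from tree")
})

test_that("collapse_low_support contracts weak internal branches", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  tr$node.label <- c("", "95", "40")
  out <- collapse_low_support(tr, cutoff = 90)
  # the 40-support (c,d) clade dissolves; the 95 one stays
  expect_lt(out$Nnode, tr$Nnode)
  expect_true(!is.null(ape::getMRCA(out, c("a", "b"))))
})
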