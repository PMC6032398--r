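# Global alignment, identity matrices, NJ trees, bootstrap, group cohesion.

test_that("percent identity is exact on simple pairs", {
  expect_equal(global_align("ACDEFGHIK", "ACDEFGHIK")$identity, 100)
  # one substitution, no gaps optimal: 8/9
  expect_equal(global_align("ACDEFGHIK", "ACDEFGHIR")$identity, 800 / 9)
  # shorter-sequence denominator
  expect_equal(global_align("ACDEF", "ACDEFGHIK")$identity, 100)
  expect_equal(global_align("ACDEF", "ACDEFGHIK",
                            identity_denom = "aligned")$identity, 100 * 5 / 9)
  expect_error(global_align("", "ACD"), "empty")
})

test_that("affine-gap alignment scores match brute-force path enumeration", {
  submat <- cellumod:::get_submat("BLOSUM62")
  set.seed(3)
  for (i in 1:25) {
    a <- paste0(sample(aa_alphabet(), sample(2:6, 1), replace = TRUE), collapse = "")
    b <- paste0(sample(aa_alphabet(), sample(2:6, 1), replace = TRUE), collapse = "")
    got <- global_align(a, b)$score
    want <- bf_align_score(a, b, submat)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("identity matrices are symmetric with a 100 diagonal and unique ids", {
  recs <- c(s1 = "MKVLAGGWYDAGDNA", s2 = "MKVLAGGWYDAGDNA", s3 = "WWWHHHHQQQNNNDD")
  im <- identity_matrix(recs)
  expect_equal(unname(diag(im$values)), rep(100, 3))
  expect_identical(im$values, t(im$values))
  expect_equal(im$values["s1", "s2"], 100)  # identical pair off-diagonal
  expect_lt(im$values["s1", "s3"], 50)
  expect_error(identity_matrix(c(a = "ACD", a = "ACD")), "duplicate")
  expect_error(identity_matrix(c(a = "ACD")), "at least two")
})

test_that("mean identity decreases as the substitution rate grows", {
  means <- vapply(c(0.02, 0.1, 0.3), function(r) {
    fam <- make_two_clade_family(n_per_clade = 3, len = 200,
                                 rate_between = r, rate_within = r, seed = 91)
    im <- identity_matrix(fam$seqs)
    mean(im$values[upper.tri(im$values)])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("group identity ranges are cross-group min/max", {
  vals <- matrix(100, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  vals["a", "c"] <- vals["c", "a"] <- 40.0
  vals["a", "d"] <- vals["d", "a"] <- 35.5
  vals["b", "c"] <- vals["c", "b"] <- 33.0
  vals["b", "d"] <- vals["d", "b"] <- 38.0
  vals["a", "b"] <- vals["b", "a"] <- 90.0
  vals["c", "d"] <- vals["d", "c"] <- 85.0
  im <- structure(list(labels = letters[1:4], values = vals,
                       groups = c(a = "g1", b = "g1", c = "g2", d = "g2")),
                  class = "identity_matrix")
  expect_equal(unname(group_identity_range(im, "g1", "g2")), c(33.0, 40.0))
  expect_equal(unname(group_identity_range(im, "g1", "g1")), c(90.0, 90.0))
  expect_error(group_identity_range(im, "g1", "nope"), "unknown group")
})

test_that("cross-group clones give a degenerate (100, 100) range", {
  recs <- c(x1 = "MKVLAGGWYDAGDNA", y1 = "MKVLAGGWYDAGDNA")
  im <- identity_matrix(recs, groups = c(x1 = "gx", y1 = "gy"))
  expect_equal(unname(group_identity_range(im, "gx", "gy")), c(100, 100))
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  bl <- stats::setNames(tree$edge.length,
                        c(tree$tip.label, rep(NA, tree$Nnode))[tree$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
})

test_that("a star matrix collapses to zero-length internal branches after clamping", {
  n <- 5
  d <- matrix(10, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  diag(d) <- 0
  tree <- nj_tree(d)
  internal <- tree$edge[, 2] > length(tree$tip.label)
  expect_true(all(tree$edge.length[internal] == 0))
  expect_true(all(tree$edge.length >= 0))
})

test_that("NJ recovers additive trees exactly (quartet oracle)", {
  set.seed(29)
  for (i in 1:15) {
    case <- random_additive_case(sample(4:8, 1))
    tree <- nj_tree(case$d)
    expect_true(all_quartets_agree(case$d, tree))
  }
})

test_that("an alignment without variable columns bootstraps to full support", {
  aln <- c(a = "AAAA", b = "CCCC", c = "GGGG", d = "TTTT")
  aln <- c(a = strrep("ACDEF", 10), b = strrep("ACDEW", 10),
           c = strrep("GHIKL", 10), d = strrep("GHIKV", 10))
  tree <- bootstrap_support(aln, n_replicates = 20, seed = 4)
  sup <- attr(tree, "supports")
  expect_true(all(sup == 1))
})

test_that("single-replicate bootstrap supports are 0 or 1", {
  fam <- make_two_clade_family(n_per_clade = 3, len = 120, seed = 8)
  tree <- bootstrap_support(fam$seqs, n_replicates = 1, seed = 9)
  expect_true(all(attr(tree, "supports") %in% c(0, 1)))
})

test_that("group cohesion reads bipartitions off the unrooted tree", {
  coh <- group_cohesion(ape::read.tree(text = "((A1,A2),(B1,B2));"),
                        c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  expect_true(all(coh))
  mix <- group_cohesion(ape::read.tree(text = "((A1,B1),(A2,B2));"),
                        c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  expect_false(any(mix))
  # trivial groups are always cohesive
  one <- group_cohesion(ape::read.tree(text = "((A1,B1),(B2,B3));"),
                        c(A1 = "A", B1 = "B", B2 = "B", B3 = "B"))
  expect_true(all(one))
})

test_that("a two-clade family yields cohesive groups with strong central support", {
  fam <- make_two_clade_family(n_per_clade = 4, len = 300,
                               rate_between = 0.3, rate_within = 0.02, seed = 10)
  tree <- bootstrap_support(fam$seqs, n_replicates = 50, seed = 11)
  expect_true(all(group_cohesion(tree, fam$groups)))
  key <- paste(sort(paste0("A", 1:4)), collapse = "|")
  expect_gte(attr(tree, "supports")[[key]], 0.95)
})
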