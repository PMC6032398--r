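# Relative quantities, geNorm stability, normalization, group comparison.

# small handmade table: 2 refs + 1 target, 2+2 samples
toy_cq <- function(cq_target = c(24, 24, 22, 22)) {
  cq <- cbind(ref1 = c(20, 20, 20, 20), ref2 = c(22, 22, 22, 22),
              ref3 = c(23, 23.5, 23, 23.5), tgt = cq_target)
  rownames(cq) <- c("c1", "c2", "t1", "t2")
  cq_table(cq,
           groups = c(c1 = "control", c2 = "control", t1 = "treated", t2 = "treated"),
           efficiency = c(ref1 = 2, ref2 = 2, ref3 = 2, tgt = 2),
           role = c(ref1 = "reference_candidate", ref2 = "reference_candidate",
                    ref3 = "reference_candidate", tgt = "target"))
}

test_that("relative quantities are efficiency powers of the calibrator delta", {
  ct <- toy_cq()
  rq <- relative_quantities(ct)
  expect_equal(unname(rq[, "ref1"]), rep(1, 4))          # equal Cq -> rq 1
  expect_equal(unname(rq[c("c1", "t1"), "tgt"]), c(0.5, 2))  # 2^(23-24), 2^(23-22)
  # with E = 1.9, the rq ratio across one cycle is exactly 1.9
  cq <- cbind(g = c(20, 21), r1 = c(10, 10), r2 = c(10, 10))
  rownames(cq) <- c("s1", "s2")
  ct2 <- cq_table(cq, groups = c(s1 = "control", s2 = "treated"),
                  efficiency = c(g = 1.9, r1 = 2, r2 = 2),
                  role = c(g = "target", r1 = "reference_candidate",
                           r2 = "reference_candidate"))
  rq2 <- relative_quantities(ct2)
  expect_equal(rq2["s1", "g"] / rq2["s2", "g"], 1.9)
})

test_that("Cq table validation enforces efficiencies, roles and completeness", {
  cq <- cbind(a = c(20, 21), b = c(22, 23))
  rownames(cq) <- c("s1", "s2")
  groups <- c(s1 = "control", s2 = "treated")
  role <- c(a = "reference_candidate", b = "target")
  expect_error(cq_table(cq, groups, c(a = 2.5, b = 2), role), "\\(1, 2\\]")
  expect_error(cq_table(cq, groups, c(a = 1, b = 2), role), "\\(1, 2\\]")
  cq_na <- cq; cq_na[1, "a"] <- NA
  expect_error(cq_table(cq_na, groups, c(a = 2, b = 2), role), "missing Cq")
})

test_that("geNorm M is exactly zero for proportional genes and ranks stability", {
  ct <- toy_cq()
  rq <- relative_quantities(ct)
  stab <- genorm_stability(rq, c("ref1", "ref2", "ref3"))
  # ref1 and ref2 are perfectly proportional: their pairwise term is 0, so
  # their M equals the sd against ref3 alone and is the smallest
  expect_identical(stab$chosen_refs, c("ref1", "ref2"))
  expect_identical(stab$elimination_order, "ref3")
  pair_sd <- stats::sd(log2(rq[, "ref1"] / rq[, "ref2"]))
  expect_equal(pair_sd, 0)
  expect_length(stab$chosen_refs, 2L)
  expect_error(genorm_stability(rq, c("ref1", "ref2")), "at least 3")
})

test_that("a noise-destabilized candidate is eliminated first", {
  plan <- default_cq_plan()
  plan$genes$sigma[plan$genes$gene == "tbpA"] <- 1.0
  plan$genes$sigma[plan$genes$sigma == 0.15 & plan$genes$role == "reference_candidate"] <- 0.05
  wins <- 0L
  for (s in 1:20) {
    ct <- make_cq_dataset(plan, seed = 7000 + s)
    rq <- relative_quantities(ct)
    stab <- genorm_stability(rq, c("eef1", "rpl23", "tbpA", "tubA1"))
    if (stab$elimination_order[1] == "tbpA") wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("normalization factors are geometric means and NRQ divides exactly", {
  ct <- toy_cq()
  rq <- relative_quantities(ct)
  rq_mod <- rq
  rq_mod["c1", c("ref1", "ref2")] <- c(4, 1)
  norm <- normalize_rq(rq_mod, c("ref1", "ref2"))
  expect_equal(unname(norm$nf[["c1"]]), 2)   # geometric mean of 4 and 1
  expect_equal(norm$nrq, rq_mod / norm$nf)
  expect_true(all(norm$nf > 0))
  # refs identically 1 leave rq untouched
  norm2 <- normalize_rq(rq, c("ref1", "ref2"))
  expect_equal(norm2$nrq[, "tgt"], rq[, "tgt"])
})

test_that("identical groups give fold change 1 and p-value 1", {
  ct <- toy_cq(cq_target = c(24, 23, 24, 23))
  res <- nrq_analysis(ct)
  cmp <- res$comparison
  expect_equal(cmp$fold_change, 1)
  expect_equal(cmp$p_value, 1)
  expect_identical(cmp$flag, "ok")
})

test_that("zero within-group variance is flagged degenerate", {
  ct <- toy_cq(cq_target = c(24, 24, 22, 22))
  res <- nrq_analysis(ct)
  expect_identical(res$comparison$flag, "degenerate")
  expect_true(is.na(res$comparison$p_value))
  expect_equal(res$comparison$fold_change, 4)  # 2 cycles at E = 2
})

test_that("NRQ fold changes are invariant to a constant shift of one gene's Cq", {
  plan <- default_cq_plan()
  ct <- make_cq_dataset(plan, seed = 314)
  base <- nrq_analysis(ct)$comparison
  for (gene in c("eef1", "cel51468")) {
    cq2 <- ct$cq
    cq2[, gene] <- cq2[, gene] + 3
    ct2 <- cq_table(cq2, ct$groups, ct$efficiency, ct$role)
    shifted <- nrq_analysis(ct2)$comparison
    expect_equal(shifted$fold_change, base$fold_change, tolerance = 1e-12)
    expect_equal(shifted$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("a planted 4x effect at low noise is reliably significant", {
  plan <- default_cq_plan()
  plan$genes$sigma <- 0.1
  plan$genes$log2_fc[plan$genes$gene == "cel51468"] <- 2
  hits <- 0L
  for (s in 1:20) {
    ct <- make_cq_dataset(plan, seed = 8000 + s)
    cmp <- nrq_analysis(ct)$comparison
    if (cmp$p_value[cmp$gene == "cel51468"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("planted log2 fold changes are recovered with small bias", {
  plan <- default_cq_plan()
  est <- vapply(1:30, function(s) {
    ct <- make_cq_dataset(plan, seed = 9000 + s)
    cmp <- nrq_analysis(ct)$comparison
    cmp$log2_fc[cmp$gene == "cel51468"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.1)
})

test_that("Cq tables round-trip through the TSV reader/writer", {
  ct <- make_cq_dataset(seed = 5)
  d <- tempfile(); dir.create(d)
  write_cq_tsv(ct, file.path(d, "cq.tsv"), file.path(d, "genes.tsv"),
               file.path(d, "samples.tsv"))
  ct2 <- read_cq_tsv(file.path(d, "cq.tsv"), file.path(d, "genes.tsv"),
                     file.path(d, "samples.tsv"))
  expect_equal(ct2$cq, ct$cq, tolerance = 1e-9)
  expect_identical(unname(ct2$role), unname(ct$role))
  expect_identical(unname(ct2$groups), unname(ct$groups))
})
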