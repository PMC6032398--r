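# Region I/II/III annotation, catalytic roles, insertion detection,
# variation profiles.

test_that("a synthetic canonical CD yields the three regions in order, flagged canonical", {
  cd <- make_cd(seed = 101)
  fr <- find_regions(protein_record("cd", cd$seq))
  expect_identical(fr$region, c("I", "II", "III"))
  expect_true(all(fr$canonical))
  expect_true(all(diff(fr$start) > 0))
  # the generator's recorded Region I/II coordinates are recovered exactly
  expect_identical(fr$start[1:2], cd$regions$start[1:2])
  expect_identical(fr$end[1:2], cd$regions$end[1:2])
})

test_that("a bare Region I site annotates as Region I only and is not canonical", {
  fr <- find_regions(protein_record("frag", "LAGGWYDAGDNAKFAFPM"))
  expect_identical(fr$region, "I")
  expect_false(any(fr$canonical))
})

test_that("a random 200-mer contains no Region I site", {
  set.seed(77)
  seq <- paste0(sample(aa_alphabet(), 200, replace = TRUE), collapse = "")
  fr <- find_regions(protein_record("rand", seq))
  expect_false("I" %in% fr$region)
})

test_that("a double-CD protein yields two canonical region triads", {
  rec <- make_protein("Gp51468", seed = 5)
  fr <- find_regions(rec)
  expect_identical(sort(unique(fr$cd)), c(1L, 2L))
  expect_identical(fr$region[fr$cd == 1L], c("I", "II", "III"))
  expect_identical(fr$region[fr$cd == 2L], c("I", "II", "III"))
  expect_true(all(fr$canonical))
})

test_that("DAGD catalytic roles are assigned, with non-canonical bases flagged", {
  rec <- protein_record("r1", "LAGGWYDAGDNAKFAFPM")
  fr <- find_regions(rec)
  roles <- catalytic_residues(fr[1, ], rec)
  expect_identical(roles$role, c("support", "base"))
  expect_identical(roles$position, c(7L, 10L))
  expect_identical(roles$residue, c("D", "D"))
  # N in place of the catalytic base D (as in some angiosperm enzymes)
  rec2 <- protein_record("r2", "LAGGWYDAGNNAKFAFPM")
  fr2 <- find_regions(rec2)
  roles2 <- catalytic_residues(fr2[1, ], rec2)
  expect_identical(roles2$role, c("support", "non_canonical_base"))
  expect_identical(roles2$residue[2], "N")
  # roles always agree with the underlying sequence letters
  for (i in seq_len(nrow(roles))) {
    expect_identical(substring(rec$seq, roles$position[i], roles$position[i]),
                     roles$residue[i])
  }
})

test_that("Region III roles are the acid/nucleophile anchors; Region II has none", {
  cd <- make_cd(seed = 33)
  rec <- protein_record("cd", cd$seq)
  fr <- find_regions(rec)
  r3 <- catalytic_residues(fr[fr$region == "III", ], rec)
  expect_identical(r3$role, c("acid", "nucleophile"))
  expect_identical(r3$residue, c("E", "D"))
  expect_identical(nrow(catalytic_residues(fr[fr$region == "II", ], rec)), 0L)
})

test_that("the Region II insertion is detected by its pattern, not its provenance", {
  mk <- function(core) {
    cd <- make_cd(seed = 9, insertion = FALSE)
    reg2 <- find_regions(protein_record("x", cd$seq))
    reg2 <- reg2[reg2$region == "II", ]
    # splice a 4-mer right after the Region II start
    at <- reg2$start + 4L
    seq <- paste0(substring(cd$seq, 1, at), core, substring(cd$seq, at + 1))
    list(rec = protein_record("x", seq), reg2 = reg2)
  }
  for (case in list(c("PTPY", TRUE), c("PTAS", TRUE), c("PSPY", FALSE))) {
    m <- mk(case[1])
    reg2 <- m$reg2
    reg2$end <- reg2$end + 4L  # span widened by the splice
    hit <- detect_insertion(reg2, m$rec)
    if (as.logical(case[2])) {
      expect_identical(hit$end - hit$start + 1L, 4L)
    } else {
      expect_null(hit)
    }
  }
})

test_that("generated CDs carry the insertion iff requested", {
  for (s in 1:5) {
    with_ins <- make_cd(seed = 200 + s, insertion = TRUE)
    rec <- protein_record("y", with_ins$seq)
    fr <- find_regions(rec)
    hit <- detect_insertion(fr[fr$region == "II", ], rec)
    expect_identical(c(hit$start, hit$end), as.integer(with_ins$insertion))
    without <- make_cd(seed = 300 + s, insertion = FALSE)
    rec2 <- protein_record("z", without$seq)
    fr2 <- find_regions(rec2)
    expect_null(detect_insertion(fr2[fr2$region == "II", ], rec2))
  }
})

test_that("variation profiles count residues and gaps with exact fractions", {
  prof <- variation_profile(c(a = "DD", b = "DN", c = "D-"))
  expect_identical(prof$columns[[1]]$freq, c(D = 1))
  col2 <- prof$columns[[2]]
  expect_identical(col2$freq, c(D = 1 / 3, N = 1 / 3))
  expect_equal(col2$gap, 1 / 3)
  expect_equal(sum(col2$freq) + col2$gap, 1, tolerance = 1e-12)
  expect_error(variation_profile(c("AB", "ABC")), "ragged")
  expect_error(variation_profile(c("AB", "AB"), column_range = 3), "bounds")
})

test_that("consensus strings honor the threshold, ties and gap majorities", {
  prof <- variation_profile(c("DAGD-", "DAGN-", "DAND-", "DAGDD", "NAGDD"))
  # col1 D:0.8; col2 A:1; col3 G:0.8; col4 D:0.8; col5 gap 0.6
  expect_identical(consensus_string(prof, 0.75), "DAGD-")
  # threshold above the top fraction renders x
  expect_identical(consensus_string(prof, 0.9), "xAxx-")
  # tie below threshold: {D:0.4, N:0.4, gap:0.2}
  tie <- variation_profile(c("D", "D", "N", "N", "-"))
  expect_identical(consensus_string(tie, 0.5), "x")
  expect_error(consensus_string(tie, 0), "threshold")
})

test_that("the consensus of an evolved CD family still reads DAGD in Region I", {
  cd <- make_cd(seed = 55)
  tree <- ape::stree(20, "star")  # 20 sequences, each 5% diverged from the root
  leaves <- evolve_on_tree(cd$seq, tree, rate = 0.05, seed = 57)
  r1 <- cd$regions[cd$regions$region == "I", ]
  prof <- variation_profile(leaves, column_range = r1$start:r1$end)
  cons <- consensus_string(prof, threshold = 0.5)
  expect_match(cons, "DAGD", fixed = TRUE)
})

test_that("region annotations export as a GFF-like protein-coordinate table", {
  rec <- make_protein("Cr9B", seed = 12)
  fr <- find_regions(rec)
  gff <- regions_to_gff(fr, stats::setNames(list(rec), rec$id))
  expect_identical(gff$type, c("region_I", "region_II", "region_III"))
  expect_identical(gff$source, rep("cellumod", 3))
  expect_match(gff$attributes[1], "roles=support:")
  expect_match(gff$attributes[2], "insertion=")
})
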