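# Composition, linker classification, CBM detection and architecture assembly.

test_that("window composition returns exact count fractions", {
  f <- composition("PSPSPSPSPS")
  expect_equal(f[["P"]], 0.5)
  expect_equal(f[["S"]], 0.5)
  f2 <- composition("AAAAAAAAAA")
  expect_equal(unname(f2[c("P", "S", "T")]), c(0, 0, 0))
  expect_equal(f2[["A"]], 1)
  f3 <- composition("PTPTSTST")
  expect_equal(unname(f3[c("P", "S", "T")]), c(0.25, 0.25, 0.5))
  expect_equal(sum(composition("LAGGWYDAGD")), 1)
  expect_error(composition(""), "empty")
})

test_that("linkers classify as PS-rich, PST-rich or non-PST by composition", {
  expect_identical(classify_linker("PSPSPSAPSPSPAA"), "PS_rich")
  expect_identical(classify_linker("PTSTPTSTPTST"), "PST_rich")
  expect_identical(classify_linker("GAGAGAGAGAGA"), "non_PST")
  expect_error(classify_linker("PSPSPS"), "minimum")
})

test_that("linker classification is invariant to sequence reversal", {
  set.seed(8)
  for (class in c("PS_rich", "PST_rich", "non_PST")) {
    for (i in 1:10) {
      s <- make_linker_seq_for_test(class, sample(12:40, 1))
      rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
      expect_identical(classify_linker(s), classify_linker(rev_s))
    }
  }
})

test_that("generated linkers always hit their class definition", {
  set.seed(21)
  for (class in c("PS_rich", "PST_rich", "non_PST")) {
    for (i in 1:25) {
      s <- make_linker_seq_for_test(class, sample(8:40, 1))
      expect_identical(classify_linker(s), class)
    }
  }
})

test_that("cysteine-rich CBMs are detected with their motif classes and family hints", {
  for (s in 1:10) {
    a <- with_seed(400 + s, make_cbm("algal_A"))
    hostA <- paste0(strrep("A", 30), a$seq, strrep("A", 30))
    detA <- detect_cbm(hostA)
    expect_identical(nrow(detA), 1L)
    expect_identical(detA$cys_count, a$cys_count)
    expect_true(all(c("sixC", "fourC", "twoC") %in%
                      strsplit(detA$motif_classes, ",")[[1]]))
    expect_identical(detA$family_hint, "algal_A")

    b <- with_seed(500 + s, make_cbm("algal_B"))
    hostB <- paste0(strrep("A", 30), b$seq, strrep("A", 30))
    detB <- detect_cbm(hostB)
    expect_identical(nrow(detB), 1L)
    expect_identical(detB$cys_count, b$cys_count)
    expect_identical(detB$motif_classes, "twoC")
    expect_identical(detB$family_hint, "algal_B")
  }
})

test_that("cysteine-poor sequences yield no CBM candidates", {
  expect_identical(nrow(detect_cbm(strrep("AGLV", 25))), 0L)
  # seven cysteines stay below the count threshold
  seq7 <- paste0(strrep("A", 20), paste(rep("CAA", 7), collapse = ""), strrep("A", 40))
  expect_identical(nrow(detect_cbm(seq7)), 0L)
})

test_that("every reported CBM satisfies the count and fraction thresholds", {
  set.seed(61)
  for (i in 1:20) {
    n <- 260
    chars <- sample(c(aa_alphabet(), "C", "C"), n, replace = TRUE)
    det <- detect_cbm(paste0(chars, collapse = ""))
    if (nrow(det)) {
      for (j in seq_len(nrow(det))) {
        width <- det$end[j] - det$start[j] + 1L
        expect_gte(det$cys_count[j], 8L)
        expect_gte(det$cys_count[j] / width, 0.08)
        expect_true(width >= 50L && width <= 130L)
      }
    }
  }
})

test_that("the flagship architectures annotate to their published strings", {
  expect_identical(annotate_architecture(make_protein("Gp51468", seed = 1))$architecture_string,
                   "CD-linker-CD-linker-CBM")
  expect_identical(annotate_architecture(make_protein("Vc2952174", seed = 2))$architecture_string,
                   "CD-linker-CBM-linker-CBM")
  expect_identical(annotate_architecture(make_protein("Cr9C", seed = 3))$architecture_string,
                   "CD-linker-?")
  expect_identical(annotate_architecture(make_protein("Cr9D", seed = 4))$architecture_string,
                   "?-CD-linker-CBM")
})

test_that("segments tile each protein with no gaps or overlaps", {
  for (spec in names(architecture_specs())) {
    rec <- make_protein(spec, seed = 17)
    segs <- annotate_architecture(rec)$segments
    expect_identical(segs$start[1], 1L)
    expect_identical(segs$end[nrow(segs)], nchar(rec$seq))
    if (nrow(segs) > 1L) {
      expect_identical(segs$start[-1], segs$end[-nrow(segs)] + 1L)
    }
  }
})

test_that("annotation recovers the ground-truth labels, order and linker classes", {
  specs <- names(architecture_specs())
  for (spec in specs) {
    for (s in 1:3) {
      rec <- make_protein(spec, seed = 1000L * s + match(spec, specs))
      arch <- annotate_architecture(rec)
      expect_identical(arch$architecture_string, attr(rec, "truth_string"),
                       info = sprintf("%s seed %d", spec, s))
      truth_link <- rec$truth$class[rec$truth$label == "LINKER"]
      got_link <- arch$segments$class[arch$segments$label == "LINKER"]
      expect_identical(got_link, truth_link, info = spec)
      truth_fam <- rec$truth$family[rec$truth$label == "CBM"]
      got_fam <- arch$segments$family_hint[arch$segments$label == "CBM"]
      expect_identical(got_fam, truth_fam, info = spec)
    }
  }
})
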