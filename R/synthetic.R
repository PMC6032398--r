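# Synthetic-data generator: modular cellulase-like proteins with known
# ground truth, tree-evolved sequence families, and qPCR Cq tables with
# planted effects.
#
# The generator is construction-first: every emitted protein satisfies the
# detection thresholds of the segmentation module by design (linker
# compositions are built from exact residue counts, CBM cysteine layouts from
# explicit cluster spacings), so the ground-truth segment map is unambiguous.
# Background (spacer/unknown) stretches avoid cysteine (CBM threshold
# residue) and glutamate (the Region III acid anchor) and down-weight P/S/T,
# so spacers never satisfy linker-richness or cysteine thresholds by chance.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` (no-op when `seed` is `NULL`),
#' restoring the caller's RNG state afterwards. All generator functions use
#' this, so a seed fully determines their output without disturbing the
#' surrounding session.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

# background residue sampler: 20 aa minus C and E, P/S/T down-weighted
background_residues <- function(n, exclude = NULL) {
  pool <- setdiff(aa_alphabet(), c("C", "E", exclude))
  w <- ifelse(pool %in% c("P", "S", "T"), 0.25, 1)
  sample(pool, n, replace = TRUE, prob = w / sum(w))
}

# one random instance of a pattern element, as a character vector
instantiate_element <- function(el, rep_count) {
  pool <- switch(el$kind,
    any = aa_alphabet(),
    class = el$residues,
    negated_class = setdiff(aa_alphabet(), el$residues)
  )
  sample(pool, rep_count, replace = TRUE)
}

# random instance of a full pattern; reps may pin chosen repeat counts
instantiate_pattern <- function(pattern, reps = NULL) {
  els <- pattern$elements
  if (is.null(reps)) {
    reps <- vapply(els, function(el) {
      if (el$min_rep == el$max_rep) el$min_rep
      else sample(el$min_rep:el$max_rep, 1L)
    }, integer(1))
  }
  parts <- Map(instantiate_element, els, reps)
  list(text = paste0(unlist(parts), collapse = ""), reps = reps)
}

#' Generate a synthetic GH9 catalytic domain
#'
#' Instantiates Regions I, II and III from their patterns (one residue drawn
#' uniformly per class position; algal CDs pin the characteristic DAGD tetrad
#' in Region I), joined by background spacers, with a
#' 30-aa head before Region I and a 60-aa tail after Region III (matching the
#' CD padding used by the segmentation stage). The algal-specific
#' four-residue insertion is placed inside Region II iff `insertion` is set
#' (realised inside the x(1,5) stretch, so the region pattern still matches);
#' when unset, instances accidentally containing an insertion-like motif are
#' re-drawn.
#'
#' @param seed Optional integer seed.
#' @param algal Algal-type CD flag (non-algal CDs never receive the
#'   insertion).
#' @param insertion Place the Region II insertion (default: `algal`).
#' @param patterns Pattern set (packaged defaults).
#' @param head,tail Background padding before Region I / after Region III.
#' @param spacer Range (2-vector) of the inter-region spacer lengths.
#' @return List with `seq`, `regions` (ground-truth data frame: `region`,
#'   `start`, `end`), and `insertion` (`c(start, end)` or `NULL`).
#' @export
make_cd <- function(seed = NULL, algal = TRUE, insertion = algal,
                    patterns = gh9_patterns(),
                    head = 30L, tail = 60L, spacer = c(30L, 60L)) {
  if (!algal) insertion <- FALSE
  with_seed(seed, {
    for (try in 1:50) {
      s12 <- sample(spacer[1]:spacer[2], 1L)
      s23 <- sample(spacer[1]:spacer[2], 1L)
      r1 <- instantiate_pattern(patterns$region1)$text
      if (algal) {
        # algal Region I characteristically carries the literal DAGD tetrad
        substring(r1, 8, 8) <- "A"
        substring(r1, 10, 10) <- "D"
      }

      # Region II: pin the x(1,5) stretch to 1 and widen it with the insertion
      reps2 <- vapply(patterns$region2$elements, function(el) {
        if (el$min_rep == el$max_rep) el$min_rep
        else sample(el$min_rep:el$max_rep, 1L)
      }, integer(1))
      ins_text <- NULL
      ins_offset <- NA_integer_
      if (insertion) {
        wide <- which(vapply(patterns$region2$elements, function(el) {
          el$kind == "any" && el$max_rep - el$min_rep >= 4L
        }, logical(1)))
        if (!length(wide)) stop("region2 pattern has no stretch wide enough for the insertion")
        reps2[wide[1]] <- 1L
        r2_inst <- instantiate_pattern(patterns$region2, reps = reps2)
        ins_text <- paste0("PT", sample(c("P", "T", "A"), 1L),
                           sample(c("Y", "S", "G"), 1L))
        at <- sum(reps2[seq_len(wide[1])])  # insert right after the pinned x
        r2 <- paste0(substring(r2_inst$text, 1L, at), ins_text,
                     substring(r2_inst$text, at + 1L))
        ins_offset <- at + 1L
      } else {
        r2 <- instantiate_pattern(patterns$region2, reps = reps2)$text
      }

      # Region III: acid anchor E, background gap, nucleophile D; the gap
      # excludes D so the placed anchor is the leftmost pattern match
      gap3 <- sample(0:12, 1L)
      r3 <- paste0("E", paste0(background_residues(gap3, exclude = "D"),
                               collapse = ""), "D")

      seq <- paste0(
        paste0(background_residues(head), collapse = ""), r1,
        paste0(background_residues(s12), collapse = ""), r2,
        paste0(background_residues(s23), collapse = ""), r3,
        paste0(background_residues(tail), collapse = ""))

      st1 <- head + 1L
      en1 <- st1 + nchar(r1) - 1L
      st2 <- en1 + s12 + 1L
      en2 <- st2 + nchar(r2) - 1L
      st3 <- en2 + s23 + 1L
      en3 <- st3 + nchar(r3) - 1L
      regions <- data.frame(region = c("I", "II", "III"),
                            start = c(st1, st2, st3), end = c(en1, en2, en3),
                            stringsAsFactors = FALSE)
      ins_coord <- if (insertion) c(st2 + ins_offset - 1L, st2 + ins_offset + 2L)
                   else NULL

      if (!insertion) {
        # reject instances with a chance insertion-like motif near Region II
        lo <- max(1L, st2 - 6L)
        hi <- min(nchar(seq), en2 + 6L)
        if (nrow(scan_pattern(patterns$insertion, substring(seq, lo, hi)))) next
      }
      return(list(seq = seq, regions = regions, insertion = ins_coord))
    }
    stop("failed to generate an insertion-free catalytic domain in 50 draws")
  })
}

# linker with an exactly controlled composition
make_linker_seq <- function(class, len) {
  stopifnot(len >= 8L)
  chars <- switch(class,
    PS_rich = {
      nP <- round(0.30 * len); nS <- round(0.30 * len)
      c(rep("P", nP), rep("S", nS),
        sample(setdiff(aa_alphabet(), c("C", "E", "P", "S", "T")),
               len - nP - nS, replace = TRUE))
    },
    PST_rich = {
      nP <- round(0.20 * len); nS <- round(0.15 * len); nT <- round(0.20 * len)
      c(rep("P", nP), rep("S", nS), rep("T", nT),
        sample(setdiff(aa_alphabet(), c("C", "E", "P", "S", "T")),
               len - nP - nS - nT, replace = TRUE))
    },
    non_PST = sample(setdiff(aa_alphabet(), c("C", "E", "P", "S", "T")),
                     len, replace = TRUE),
    stop(sprintf("unknown linker class '%s'", class))
  )
  paste0(sample(chars), collapse = "")
}

# cysteine layout of a CBM; returns a character vector
# algal_A: one 6-C cluster (2-aa gaps) + one 4-C cluster (3-aa gaps) + extra
#          2-C pairs; algal_B: 2-C pairs only (plus one isolated C when the
#          total is odd), spaced so no 4-C/6-C class can arise
cbm_chars <- function(family, total_cys) {
  stopifnot(total_cys >= 10L, total_cys <= 16L)
  gap <- function(k) background_residues(k)
  chars <- character(0)
  pair <- function() c("C", gap(2L), "C")
  if (family == "algal_A") {
    six <- c("C", gap(2L), "C", gap(2L), "C", gap(2L), "C", gap(2L), "C", gap(2L), "C")
    four <- c("C", gap(3L), "C", gap(3L), "C", gap(3L), "C")
    chars <- c(six, gap(10L), four)
    extra <- total_cys - 10L
    for (i in seq_len(extra %/% 2L)) chars <- c(chars, gap(13L), pair())
    if (extra %% 2L) chars <- c(chars, gap(13L), "C")
  } else if (family == "algal_B") {
    pairs <- total_cys %/% 2L
    chars <- pair()
    for (i in seq_len(pairs - 1L)) chars <- c(chars, gap(13L), pair())
    if (total_cys %% 2L) chars <- c(chars, gap(13L), "C")
  } else {
    stop(sprintf("unknown CBM family '%s'", family))
  }
  chars
}

#' Generate a synthetic cysteine-rich CBM segment
#'
#' Total cysteines are drawn uniformly from 10 to 16 (the range observed in
#' algal cellulase CBMs). `algal_A` segments carry one 6-C cluster, one 4-C
#' cluster and any remaining cysteines as 2-C pairs; `algal_B` segments carry
#' 2-C pairs only, spaced so that no 4-C or 6-C class can arise.
#'
#' @param family `"algal_A"` or `"algal_B"`.
#' @param seed Optional integer seed.
#' @param total_cys Cysteine count (default: drawn uniformly from 10:16).
#' @return List with `seq` and `cys_count`.
#' @export
make_cbm <- function(family, seed = NULL, total_cys = NULL) {
  with_seed(seed, {
    if (is.null(total_cys)) total_cys <- sample(10:16, 1L)
    core <- cbm_chars(family, total_cys)
    span <- length(core)
    flank <- max(4L, ceiling((54L - span) / 2))
    seq <- paste0(c(background_residues(flank), core, background_residues(flank)),
                  collapse = "")
    list(seq = seq, cys_count = total_cys)
  })
}

#' The eight modular architecture blueprints
#'
#' Segment plans for the eight studied algal cellulases: single- and
#' double-CD architectures, one or two C-terminal CBMs of either proposed
#' family, classified linkers, an Ig-like/unknown C-terminal domain (Cr9C)
#' and an unknown N-terminal stretch (Cr9D). The Region II insertion is on
#' for every algal CD except those of Cr9D and Gp44756.
#'
#' @return Named list of segment plans (each a list of segment descriptors).
#' @export
architecture_specs <- function() {
  cd <- function(ins) list(kind = "CD", insertion = ins)
  lnk <- function(class) list(kind = "LINKER", class = class)
  cbm <- function(family) list(kind = "CBM", family = family)
  unk <- function() list(kind = "UNKNOWN")
  list(
    Cr9B      = list(cd(TRUE), lnk("non_PST"), cbm("algal_A")),
    Cr9C      = list(cd(TRUE), lnk("non_PST"), unk()),
    Cr9D      = list(unk(), cd(FALSE), lnk("PST_rich"), cbm("algal_B")),
    Gp51466   = list(cd(TRUE), lnk("non_PST"), cbm("algal_A")),
    Gp51468   = list(cd(TRUE), lnk("PS_rich"), cd(TRUE), lnk("non_PST"), cbm("algal_A")),
    Gp44756   = list(cd(FALSE), lnk("non_PST"), cbm("algal_B")),
    Vc2952174 = list(cd(TRUE), lnk("non_PST"), cbm("algal_B"), lnk("PS_rich"), cbm("algal_B")),
    Vc2958622 = list(cd(TRUE), lnk("PS_rich"), cbm("algal_A"))
  )
}

#' Generate a synthetic modular cellulase protein
#'
#' Renders an architecture blueprint into a concrete sequence with a
#' ground-truth segment map: CDs via [make_cd()], linkers with exact-count
#' compositions hitting their class definitions with margin, CBMs via
#' [make_cbm()], and background filler for unknown (e.g. Ig-like) stretches.
#'
#' @param spec Blueprint name (see [architecture_specs()]) or a segment plan.
#' @param seed Optional integer seed (fully determines the output).
#' @param linker_len,unknown_len Length ranges for linkers and unknown
#'   stretches.
#' @param patterns Pattern set for CD generation.
#' @return A `protein_record` whose `truth` field holds the ground-truth
#'   segments (`label`, `start`, `end`, `class`, `family`, `cys_count`) and
#'   whose `truth_string` attribute holds the reference architecture string.
#' @export
make_protein <- function(spec, seed = NULL,
                         linker_len = c(20L, 40L), unknown_len = c(70L, 90L),
                         patterns = gh9_patterns()) {
  if (is.character(spec)) {
    plans <- architecture_specs()
    if (!spec %in% names(plans)) stop(sprintf("unknown architecture spec '%s'", spec))
    id <- spec
    plan <- plans[[spec]]
  } else {
    id <- "synthetic"
    plan <- spec
  }
  with_seed(seed, {
    segs <- list()
    pieces <- character(0)
    pos <- 0L
    push <- function(label, piece, class = NA_character_,
                     family = NA_character_, cys = NA_integer_) {
      len <- nchar(piece)
      segs[[length(segs) + 1L]] <<- data.frame(
        label = label, start = pos + 1L, end = pos + len, class = class,
        family = family, cys_count = cys, stringsAsFactors = FALSE)
      pieces <<- c(pieces, piece)
      pos <<- pos + len
    }
    for (sg in plan) {
      if (sg$kind == "CD") {
        cd <- make_cd(insertion = sg$insertion, patterns = patterns)
        push("CD", cd$seq)
      } else if (sg$kind == "LINKER") {
        len <- sample(linker_len[1]:linker_len[2], 1L)
        push("LINKER", make_linker_seq(sg$class, len), class = sg$class)
      } else if (sg$kind == "CBM") {
        cb <- make_cbm(sg$family)
        push("CBM", cb$seq, family = sg$family, cys = cb$cys_count)
      } else if (sg$kind == "UNKNOWN") {
        len <- sample(unknown_len[1]:unknown_len[2], 1L)
        push("UNKNOWN", paste0(background_residues(len), collapse = ""))
      } else {
        stop(sprintf("unknown segment kind '%s'", sg$kind))
      }
    }
    truth <- do.call(rbind, segs)
    rec <- protein_record(id, paste0(pieces, collapse = ""), truth = truth)
    attr(rec, "truth_string") <- render_architecture(truth, unknown_render_min = 10L)
    rec
  })
}

#' Evolve a sequence along a tree by per-site substitution
#'
#' Each site mutates independently on each branch with the branch's
#' substitution probability (uniform replacement among the other 19
#' residues). No indels are introduced, so the leaves form an alignment.
#'
#' @param root_seq Root amino-acid sequence.
#' @param tree An \pkg{ape} `phylo` tree.
#' @param rate Per-branch substitution probability in `[0, 0.75)`; a scalar,
#'   or a vector recycled over the rows of `tree$edge`.
#' @param seed Optional integer seed.
#' @return Named character vector of leaf sequences (names = tip labels).
#' @export
evolve_on_tree <- function(root_seq, tree, rate, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (any(rate < 0 | rate >= 0.75)) {
    stop("substitution rate must lie in [0, 0.75)")
  }
  rate <- rep_len(rate, nrow(tree$edge))
  with_seed(seed, {
    tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
    root_chars <- strsplit(toupper(root_seq), "", fixed = TRUE)[[1]]
    ntip <- length(tree$tip.label)
    node_seq <- vector("list", ntip + tree$Nnode)
    node_seq[[ntip + 1L]] <- root_chars
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      chars <- node_seq[[parent]]
      hit <- which(stats::runif(length(chars)) < rate[e])
      for (i in hit) {
        chars[i] <- sample(setdiff(aa_alphabet(), chars[i]), 1L)
      }
      node_seq[[child]] <- chars
    }
    leaves <- vapply(seq_len(ntip), function(i) {
      paste0(node_seq[[i]], collapse = "")
    }, character(1))
    names(leaves) <- tree$tip.label
    leaves
  })
}

#' Two-clade study family
#'
#' A root sequence diverges into two clade ancestors (per-site substitution
#' probability `rate_between` on each stem), each of which radiates into
#' `n_per_clade` leaves at `rate_within`. Emulates the deep between-group /
#' shallow within-group divergence used in the group-clustering analyses.
#'
#' @param n_per_clade Leaves per clade.
#' @param len Sequence length.
#' @param rate_between,rate_within Stem / terminal substitution
#'   probabilities.
#' @param seed Optional integer seed.
#' @return List with `seqs` (named character vector, leaves `A1..`/`B1..`)
#'   and `groups` (named tags `"A"`/`"B"`).
#' @export
make_two_clade_family <- function(n_per_clade = 4L, len = 300L,
                                  rate_between = 0.3, rate_within = 0.02,
                                  seed = NULL) {
  with_seed(seed, {
    mutate <- function(chars, p) {
      hit <- which(stats::runif(length(chars)) < p)
      for (i in hit) chars[i] <- sample(setdiff(aa_alphabet(), chars[i]), 1L)
      chars
    }
    root <- sample(aa_alphabet(), len, replace = TRUE)
    anc <- list(A = mutate(root, rate_between), B = mutate(root, rate_between))
    seqs <- character(0)
    groups <- character(0)
    for (g in c("A", "B")) {
      for (i in seq_len(n_per_clade)) {
        nm <- paste0(g, i)
        seqs[nm] <- paste0(mutate(anc[[g]], rate_within), collapse = "")
        groups[nm] <- g
      }
    }
    list(seqs = seqs, groups = groups)
  })
}

#' Default qPCR simulation plan
#'
#' Four stable reference candidates (eef1, rpl23, tbpA, tubA1; efficiency 2,
#' i.e. 100%) and three cellulase targets with planted log2 fold changes of
#' 1, 1 and 0.15 (two clear 2x upregulations plus one sub-significant trend,
#' the qualitative pattern observed for the three studied cellulases),
#' measurement noise 0.15 cycles, six samples per group.
#'
#' @return A plan list for [make_cq_dataset()].
#' @export
default_cq_plan <- function() {
  list(
    genes = data.frame(
      gene = c("eef1", "rpl23", "tbpA", "tubA1",
               "cel51466", "cel51468", "cel44756"),
      efficiency = 2,
      role = c(rep("reference_candidate", 4), rep("target", 3)),
      base_cq = c(21, 23, 26, 24, 28, 29, 27),
      sigma = 0.15,
      log2_fc = c(0, 0, 0, 0, 1, 1, 0.15),
      stringsAsFactors = FALSE),
    n_control = 6L, n_treated = 6L
  )
}

#' Simulate a qPCR Cq dataset with planted effects
#'
#' Cq(s, g) = base_g - effect(s, g) / log2(E_g) + N(0, sigma_g), where the
#' effect is the planted log2 fold change for treated samples of target
#' genes and zero otherwise (so a planted log2 FC of 1 with E = 2 lowers the
#' treated Cq by exactly one cycle before noise).
#'
#' @param plan Plan list (see [default_cq_plan()]): `genes` data frame with
#'   `gene`, `efficiency`, `role`, `base_cq`, `sigma`, `log2_fc`;
#'   `n_control`, `n_treated`.
#' @param seed Optional integer seed (fully determines the table).
#' @return A [cq_table()]; the plan is attached as the `plan` attribute.
#' @export
make_cq_dataset <- function(plan = default_cq_plan(), seed = NULL) {
  g <- plan$genes
  if (sum(g$role == "reference_candidate") < 3L) {
    stop("plan needs at least 3 reference candidates")
  }
  with_seed(seed, {
    samples <- c(paste0("ctrl", seq_len(plan$n_control)),
                 paste0("trt", seq_len(plan$n_treated)))
    groups <- stats::setNames(
      rep(c("control", "treated"), c(plan$n_control, plan$n_treated)), samples)
    cq <- matrix(NA_real_, nrow = length(samples), ncol = nrow(g),
                 dimnames = list(samples, g$gene))
    for (j in seq_len(nrow(g))) {
      effect <- ifelse(groups == "treated" & g$role[j] == "target",
                       g$log2_fc[j], 0)
      cq[, j] <- g$base_cq[j] - effect / log2(g$efficiency[j]) +
        stats::rnorm(length(samples), 0, g$sigma[j])
    }
    ct <- cq_table(cq, groups = groups,
                   efficiency = stats::setNames(g$efficiency, g$gene),
                   role = stats::setNames(g$role, g$gene))
    attr(ct, "plan") <- plan
    ct
  })
}

#' Simulate the full eight-architecture protein panel
#'
#' @param seed Integer seed.
#' @param out_dir Optional directory; writes `proteins.fasta` and
#'   `truth_segments.tsv` (byte-identical for identical seeds).
#' @param config Configuration recorded in TSV headers.
#' @return Named list of `protein_record`s (one per blueprint).
#' @export
simulate_panel <- function(seed = 1L, out_dir = NULL,
                           config = pipeline_config()) {
  specs <- names(architecture_specs())
  recs <- with_seed(seed, lapply(specs, make_protein))
  names(recs) <- specs
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(recs, file.path(out_dir, "proteins.fasta"))
    truth <- do.call(rbind, lapply(recs, function(r) {
      cbind(sequence_id = r$id, r$truth)
    }))
    rownames(truth) <- NULL
    write_tsv_header(truth, file.path(out_dir, "truth_segments.tsv"), config)
  }
  recs
}
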