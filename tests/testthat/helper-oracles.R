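# Independent oracles used by the property-style tests.

# --- brute-force PROSITE matcher -------------------------------------------
# Enumerates every substring and every wildcard-length assignment by direct
# recursion over pattern elements; shares no code with scan_pattern().

bf_element_match <- function(el, chars) {
  ok <- switch(el$kind,
    any = rep(TRUE, length(chars)),
    class = chars %in% el$residues | chars == "X",
    negated_class = !(chars %in% el$residues) & chars != "X"
  )
  all(ok)
}

bf_match_here <- function(els, chars) {
  if (!length(els)) return(length(chars) == 0L)
  el <- els[[1]]
  for (r in el$min_rep:el$max_rep) {
    if (r > length(chars)) break
    if (r == 0L || bf_element_match(el, chars[seq_len(r)])) {
      rest <- if (r >= length(chars)) character(0) else chars[(r + 1L):length(chars)]
      if (bf_match_here(els[-1], rest)) return(TRUE)
    }
  }
  FALSE
}

bf_scan <- function(pattern, seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  mins <- sum(vapply(pattern$elements, function(e) e$min_rep, integer(1)))
  maxs <- sum(vapply(pattern$elements, function(e) e$max_rep, integer(1)))
  out <- NULL
  starts <- if (pattern$n_anchor) 1L else seq_len(max(n, 0L))
  for (s in starts) {
    for (len in max(mins, 1L):maxs) {
      e <- s + len - 1L
      if (e > n) break
      if (pattern$c_anchor && e != n) next
      if (bf_match_here(pattern$elements, chars[s:e])) {
        out <- rbind(out, c(s, e))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  df <- data.frame(start = out[, 1], end = out[, 2])
  df[order(df$start, df$end), , drop = FALSE]
}

# random pattern generator for the oracle-equivalence property
random_pattern <- function(max_elements = 8L, max_repeat = 5L) {
  aa <- aa_alphabet()
  k <- sample(2:max_elements, 1L)
  els <- lapply(seq_len(k), function(i) {
    kind <- sample(c("class", "any", "negated_class"), 1L,
                   prob = c(0.6, 0.3, 0.1))
    residues <- switch(kind,
      any = character(0),
      class = sort(sample(aa, sample(1:4, 1L))),
      negated_class = sort(sample(aa, sample(15:19, 1L))))
    reps <- if (stats::runif(1) < 0.7) c(1L, 1L) else {
      lo <- sample(if (kind == "any") 0:3 else 1:3, 1L)
      hi <- sample(lo:max_repeat, 1L)
      c(lo, hi)
    }
    list(kind = kind, residues = residues,
         min_rep = as.integer(reps[1]), max_rep = as.integer(reps[2]))
  })
  structure(list(pattern_id = "rand", elements = els,
                 n_anchor = stats::runif(1) < 0.1,
                 c_anchor = stats::runif(1) < 0.1),
            class = "prosite_pattern")
}

# random subject sequence biased toward the residues a pattern can match,
# so the equivalence check exercises real matches, not just misses
random_subject <- function(pattern, max_len = 60L) {
  aa <- aa_alphabet()
  in_pat <- unique(unlist(lapply(pattern$elements, function(e) {
    if (e$kind == "class") e$residues else character(0)
  })))
  pool <- c(in_pat, in_pat, sample(aa, 5L), "X")
  n <- sample(0:max_len, 1L)
  paste0(sample(pool, n, replace = TRUE), collapse = "")
}

# --- brute-force global aligner --------------------------------------------
# Enumerates every global alignment path (match / gap-in-a / gap-in-b moves)
# and scores it under affine gaps: a gap run of length L costs open + L*ext.
# No dynamic programming: plain depth-first enumeration, feasible for tiny
# sequences only.

bf_align_score <- function(a, b, submat, gap_open = 10, gap_ext = 0.5) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- -Inf
  rec <- function(i, j, state, acc) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, "m", acc + submat[ca[i], cb[j]])
    }
    if (i <= length(ca)) {  # gap in b
      pen <- gap_ext + if (state == "ga") 0 else gap_open
      rec(i + 1L, j, "ga", acc - pen)
    }
    if (j <= length(cb)) {  # gap in a
      pen <- gap_ext + if (state == "gb") 0 else gap_open
      rec(i, j + 1L, "gb", acc - pen)
    }
  }
  rec(1L, 1L, "none", 0)
  best
}

# --- quartet (four-point) oracle for tree topologies -----------------------
# The split of a quartet {i,j,k,l} under an additive distance is the pairing
# with the smallest sum; on a tree, hop distances are additive, so the same
# rule reads the topology off a tree independently of NJ.

quartet_split <- function(d, q) {
  s1 <- d[q[1], q[2]] + d[q[3], q[4]]
  s2 <- d[q[1], q[3]] + d[q[2], q[4]]
  s3 <- d[q[1], q[4]] + d[q[2], q[3]]
  which.min(c(s1, s2, s3))
}

tree_hop_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  d <- ape::cophenetic.phylo(t2)
  d[tree$tip.label, tree$tip.label]
}

all_quartets_agree <- function(d, tree) {
  labs <- rownames(d)
  ht <- tree_hop_dist(tree)[labs, labs]
  combs <- utils::combn(seq_along(labs), 4L)
  for (c_i in seq_len(ncol(combs))) {
    q <- combs[, c_i]
    if (quartet_split(d, q) != quartet_split(ht, q)) return(FALSE)
  }
  TRUE
}

# additive distance matrix from a random tree with strictly positive branches
random_additive_case <- function(n) {
  tree <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

# thin alias for the internal linker sampler (exercised directly by tests)
make_linker_seq_for_test <- function(class, len) {
  cellumod:::make_linker_seq(class, len)
}
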