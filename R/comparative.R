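# Pairwise percent identity, identity matrices, neighbor-joining trees with
# bootstrap support, and group-cohesion checks.
#
# Identity here uses identical aligned residue pairs divided by the length of
# the shorter sequence (configurable to aligned columns). Tree inference is
# Saitou-Nei neighbor joining on d = 100 - identity: a distance-based
# stand-in exercising the same group-clustering claim as a maximum-likelihood
# tree, not a reproduction of one.

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise alignment with percent identity
#'
#' Optimal global alignment under affine gap penalties (a gap run of length L
#' costs `gap_open + L * gap_ext`) and a substitution matrix, via the Gotoh
#' recurrence as implemented in Biostrings.
#'
#' @param a,b `protein_record`s or character sequences (non-empty).
#' @param substitution_matrix Matrix name (default `"BLOSUM62"`) or matrix.
#' @param gap_open,gap_ext Affine gap penalties (default 10 and 0.5).
#' @param identity_denom `"shorter"` (identical pairs / shorter sequence
#'   length, the default) or `"aligned"` (identical pairs / alignment length).
#' @return List with `score`, `identity` (percent), `n_ident`, and the two
#'   gapped alignment strings `aligned_a`, `aligned_b`.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_ext = 0.5,
                         identity_denom = c("shorter", "aligned")) {
  identity_denom <- match.arg(identity_denom)
  ra <- as_protein_record(a, id = "a")
  rb <- as_protein_record(b, id = "b")
  if (!nchar(ra$seq) || !nchar(rb$seq)) stop("empty sequence in alignment")
  mat <- if (is.character(substitution_matrix)) get_submat(substitution_matrix)
         else substitution_matrix
  aln <- Biostrings::pairwiseAlignment(
    ra$seq, rb$seq, substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext, type = "global")
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  n_ident <- Biostrings::nmatch(aln)
  denom <- switch(identity_denom,
                  shorter = min(nchar(ra$seq), nchar(rb$seq)),
                  aligned = nchar(pa))
  list(score = Biostrings::score(aln),
       identity = 100 * n_ident / denom,
       n_ident = n_ident, aligned_a = pa, aligned_b = pb)
}

#' Pairwise percent-identity matrix
#'
#' All pairwise identities by [global_align()]; symmetric with a diagonal of
#' 100.
#'
#' @param records Named list of at least two `protein_record`s (or a named
#'   character vector; ids must be unique).
#' @param groups Optional named character vector of taxonomic group tags.
#' @param ... Passed to [global_align()].
#' @return Object of class `identity_matrix`: list with `labels`, `values`
#'   (percent matrix) and `groups`.
#' @export
identity_matrix <- function(records, groups = NULL, ...) {
  seqs <- record_seqs(records)
  if (length(seqs) < 2L) stop("need at least two records")
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id '%s'", ids[duplicated(ids)][1]))
  }
  k <- length(seqs)
  vals <- matrix(100, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pid <- global_align(seqs[[i]], seqs[[j]], ...)$identity
      vals[i, j] <- pid
      vals[j, i] <- pid
    }
  }
  if (!is.null(groups)) {
    missing <- setdiff(ids, names(groups))
    if (length(missing)) {
      stop(sprintf("no group tag for '%s'", missing[1]))
    }
    groups <- groups[ids]
  }
  structure(list(labels = ids, values = vals, groups = groups),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d sequences%s\n", length(x$labels),
              if (!is.null(x$groups))
                sprintf(", %d groups", length(unique(x$groups))) else ""))
  print(round(x$values, 1))
  invisible(x)
}

#' Identity range between two taxonomic groups
#'
#' Minimum and maximum percent identity over all cross-group pairs (or all
#' within-group off-diagonal pairs when `group_a == group_b`).
#'
#' @param matrix An `identity_matrix` with group tags.
#' @param group_a,group_b Group labels.
#' @return Numeric `c(min, max)` in percent.
#' @export
group_identity_range <- function(matrix, group_a, group_b) {
  stopifnot(inherits(matrix, "identity_matrix"))
  if (is.null(matrix$groups)) stop("identity matrix carries no group tags")
  for (g in unique(c(group_a, group_b))) {
    if (!(g %in% matrix$groups)) stop(sprintf("unknown group '%s'", g))
  }
  ia <- which(matrix$groups == group_a)
  ib <- which(matrix$groups == group_b)
  if (identical(group_a, group_b)) {
    pairs <- matrix$values[ia, ib, drop = FALSE]
    vals <- pairs[upper.tri(pairs)]
  } else {
    vals <- as.vector(matrix$values[ia, ib, drop = FALSE])
  }
  if (!length(vals)) stop("no pairs between the requested groups")
  c(min = min(vals), max = max(vals))
}

identity_to_dist <- function(im, distance_transform = c("linear", "poisson")) {
  distance_transform <- match.arg(distance_transform)
  d <- 100 - im$values
  if (distance_transform == "poisson") {
    p <- pmin(d / 100, 0.999)
    d <- -100 * log(1 - p)
  }
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from an identity matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on the distance
#' `d = 100 - identity` (optionally Poisson-corrected). Negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to zero;
#' the clamped total is kept in the `clamped_deficit` attribute.
#'
#' @param matrix An `identity_matrix` (>= 3 labels), or a plain symmetric
#'   distance matrix with dimnames.
#' @param distance_transform `"linear"` (default) or `"poisson"`.
#' @return An unrooted `phylo` tree; leaf set equals the matrix labels. Group
#'   tags, when present, are carried in the `groups` attribute.
#' @export
nj_tree <- function(matrix, distance_transform = "linear") {
  if (inherits(matrix, "identity_matrix")) {
    d <- identity_to_dist(matrix, distance_transform)
    groups <- matrix$groups
  } else {
    d <- as.matrix(matrix)
    groups <- NULL
  }
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 labels")
  tree <- ape::nj(d)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    attr(tree, "clamped_deficit") <- -sum(tree$edge.length[neg])
    tree$edge.length[neg] <- 0
  }
  attr(tree, "groups") <- groups
  tree
}

# identity between rows of an aligned character matrix:
# identical non-gap pairs / shorter ungapped length * 100
alignment_identity_matrix <- function(mat) {
  k <- nrow(mat)
  ids <- rownames(mat)
  lens <- rowSums(mat != "-")
  vals <- matrix(100, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      nid <- sum(both & mat[i, ] == mat[j, ])
      pid <- 100 * nid / min(lens[i], lens[j])
      vals[i, j] <- pid
      vals[j, i] <- pid
    }
  }
  vals
}

# canonical string keys for the non-trivial bipartitions of an unrooted tree
tree_bipartitions <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(attr(parts, "labels")[p])
    comp <- setdiff(labs, side)
    if (length(side) < 2L || length(comp) < 2L) next
    a <- paste(side, collapse = "|")
    b <- paste(comp, collapse = "|")
    keys <- c(keys, if (a < b) a else b)
  }
  unique(keys)
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement; each replicate yields an
#' identity matrix and an NJ tree. The support of a bipartition of the
#' original tree is the fraction of replicate trees containing it. Trivial
#' (leaf) bipartitions have support 1 by construction.
#'
#' @param alignment Named equal-length aligned sequences (character vector or
#'   `protein_record` list; gaps `-` allowed).
#' @param n_replicates Number of bootstrap replicates (>= 1; 100 matches the
#'   usual reporting convention).
#' @param seed Integer seed; the resampling is fully reproducible.
#' @param distance_transform Passed to the per-replicate tree build.
#' @return The NJ tree of the full alignment with `node.label` holding the
#'   support (in `[0, 1]`) of each internal bipartition, and a `supports`
#'   attribute mapping bipartition keys to support values.
#' @export
bootstrap_support <- function(alignment, n_replicates = 100L, seed = 1L,
                              distance_transform = "linear") {
  stopifnot(n_replicates >= 1L)
  seqs <- record_seqs(alignment)
  if (length(unique(nchar(seqs))) != 1L) stop("ragged alignment")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  ncol_aln <- ncol(mat)

  build <- function(m) {
    im <- structure(list(labels = rownames(m),
                         values = alignment_identity_matrix(m), groups = NULL),
                    class = "identity_matrix")
    nj_tree(im, distance_transform = distance_transform)
  }
  main <- build(mat)
  main_keys <- tree_bipartitions(main)
  counts <- stats::setNames(numeric(length(main_keys)), main_keys)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rep_keys <- tree_bipartitions(build(mat[, cols, drop = FALSE]))
    hit <- main_keys %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  supports <- counts / n_replicates
  # attach supports as internal node labels
  main$node.label <- rep(NA_character_, main$Nnode)
  for (k in seq_along(main_keys)) {
    key_tips <- strsplit(main_keys[k], "|", fixed = TRUE)[[1]]
    node <- find_bipartition_node(main, key_tips)
    if (!is.na(node)) {
      main$node.label[node - length(main$tip.label)] <-
        format(supports[k], digits = 3)
    }
  }
  attr(main, "supports") <- supports
  main
}

# internal node whose descendant tip set equals `tips` or its complement
find_bipartition_node <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  for (i in seq_along(parts)) {
    side <- sort(labs[parts[[i]]])
    comp <- sort(setdiff(labs, side))
    if (identical(side, sort(tips)) || identical(comp, sort(tips))) {
      return(ntip + i)
    }
  }
  NA_integer_
}

#' Do groups form clades on the unrooted tree?
#'
#' A group is cohesive when its leaves form one side of some bipartition of
#' the unrooted tree (trivial groups of size 1, n-1 or n are always cohesive).
#'
#' @param tree A `phylo` tree.
#' @param group_of Named character vector mapping every leaf to a group tag.
#' @return Named logical vector, one entry per group.
#' @export
group_cohesion <- function(tree, group_of) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(group_of))
  if (length(missing)) stop(sprintf("no group tag for leaf '%s'", missing[1]))
  keys <- tree_bipartitions(tree)
  labs <- sort(tips)
  vapply(unique(group_of[tips]), function(g) {
    side <- sort(tips[group_of[tips] == g])
    k <- length(side)
    if (k <= 1L || k >= length(tips) - 1L) return(TRUE)
    a <- paste(side, collapse = "|")
    b <- paste(setdiff(labs, side), collapse = "|")
    (if (a < b) a else b) %in% keys
  }, logical(1))
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
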