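# Multi-reference-gene qPCR expression analysis: efficiency-corrected
# relative quantities, geNorm reference stability (M), normalization factors,
# normalized relative quantities (NRQ), and two-group comparison.
#
# Per gene g with amplification efficiency E_g (2 = 100% doubling per cycle),
# the relative quantity of sample s is rq(s,g) = E_g^(Cq_cal - Cq(s,g)) with
# the calibrator Cq_cal the mean Cq of the gene over all samples (qbase
# convention; a control-group-mean calibrator is available). geNorm stability
# M_j is the mean, over all other candidates k, of the standard deviation
# across samples of log2(rq_j / rq_k); candidates are eliminated highest-M
# first until two remain. NRQ(s,t) = rq(s,t) divided by the geometric mean of
# the chosen references' rq in sample s.

#' Assemble a Cq table
#'
#' @param cq Numeric matrix of quantification cycles, samples in rows, genes
#'   in columns (dimnames required; positive values).
#' @param groups Named character vector mapping each sample to `"control"` or
#'   `"treated"`.
#' @param efficiency Named numeric vector of per-gene amplification
#'   efficiencies, each in (1, 2].
#' @param role Named character vector mapping each gene to `"target"` or
#'   `"reference_candidate"`.
#' @return Object of class `cq_table`.
#' @export
cq_table <- function(cq, groups, efficiency, role) {
  stopifnot(is.matrix(cq), !is.null(rownames(cq)), !is.null(colnames(cq)))
  samples <- rownames(cq)
  genes <- colnames(cq)
  if (!all(samples %in% names(groups))) stop("every sample needs a group label")
  if (!all(genes %in% names(efficiency))) stop("every gene needs an efficiency")
  if (!all(genes %in% names(role))) stop("every gene needs a role")
  groups <- groups[samples]
  efficiency <- efficiency[genes]
  role <- role[genes]
  if (!all(groups %in% c("control", "treated"))) {
    stop("groups must be 'control' or 'treated'")
  }
  if (any(efficiency <= 1 | efficiency > 2)) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  refs <- genes[role == "reference_candidate"]
  if (length(refs) && anyNA(cq[, refs])) {
    stop("missing Cq for a reference candidate")
  }
  if (any(cq <= 0, na.rm = TRUE)) stop("Cq values must be positive")
  structure(list(cq = cq, groups = groups, efficiency = efficiency, role = role),
            class = "cq_table")
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("<cq_table> %d samples (%d control / %d treated) x %d genes (%d reference candidates)\n",
              nrow(x$cq), sum(x$groups == "control"), sum(x$groups == "treated"),
              ncol(x$cq), sum(x$role == "reference_candidate")))
  invisible(x)
}

#' Efficiency-corrected relative quantities
#'
#' @param ct A [cq_table()].
#' @param calibrator `"all"` (per-gene mean Cq over all samples, the default)
#'   or `"control"` (mean over control samples).
#' @return Numeric sample x gene matrix of relative quantities.
#' @export
relative_quantities <- function(ct, calibrator = c("all", "control")) {
  stopifnot(inherits(ct, "cq_table"))
  calibrator <- match.arg(calibrator)
  idx <- if (calibrator == "all") seq_len(nrow(ct$cq))
         else which(ct$groups == "control")
  cal <- colMeans(ct$cq[idx, , drop = FALSE], na.rm = TRUE)
  rq <- ct$cq
  for (g in colnames(rq)) {
    rq[, g] <- ct$efficiency[[g]]^(cal[[g]] - ct$cq[, g])
  }
  rq
}

#' geNorm reference-gene stability
#'
#' Computes the stability value M for each candidate (mean pairwise standard
#' deviation of the log2 rq ratios against all other candidates), then
#' iteratively eliminates the least stable candidate until two remain.
#'
#' @param rq Relative-quantity matrix from [relative_quantities()].
#' @param candidates Gene names to consider (>= 3; >= 2 samples needed).
#' @return List with `stability_m` (initial M per candidate), `ranking`
#'   (most stable first; the final two share the top), `elimination_order`
#'   (least stable first) and `chosen_refs` (always the final two).
#' @export
genorm_stability <- function(rq, candidates) {
  stopifnot(is.matrix(rq))
  if (length(candidates) < 3L) stop("geNorm needs at least 3 candidate genes")
  if (nrow(rq) < 2L) stop("geNorm needs at least 2 samples")
  sub <- rq[, candidates, drop = FALSE]
  if (any(sub <= 0)) stop("relative quantities must be positive")
  lsub <- log2(sub)
  m_of <- function(genes) {
    vapply(genes, function(j) {
      others <- setdiff(genes, j)
      mean(vapply(others, function(k) stats::sd(lsub[, j] - lsub[, k]),
                  numeric(1)))
    }, numeric(1))
  }
  stability_m <- m_of(candidates)
  remaining <- candidates
  elim <- character(0)
  while (length(remaining) > 2L) {
    m <- m_of(remaining)
    worst <- names(which.max(m))
    elim <- c(elim, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(stability_m = stability_m,
       ranking = c(remaining, rev(elim)),
       elimination_order = elim,
       chosen_refs = remaining)
}

#' Multi-reference normalization
#'
#' The normalization factor of a sample is the geometric mean of the chosen
#' reference genes' relative quantities; NRQ divides each gene's rq by it.
#'
#' @param rq Relative-quantity matrix.
#' @param chosen_refs Non-empty character vector of reference gene names.
#' @return List with `nf` (per-sample factor, > 0) and `nrq` (sample x gene
#'   matrix; `nrq = rq / nf` exactly).
#' @export
normalize_rq <- function(rq, chosen_refs) {
  stopifnot(is.matrix(rq), length(chosen_refs) >= 1L,
            all(chosen_refs %in% colnames(rq)))
  nf <- exp(rowMeans(log(rq[, chosen_refs, drop = FALSE])))
  list(nf = nf, nrq = rq / nf)
}

#' Two-group comparison of normalized relative quantities
#'
#' Fold change is the ratio of NRQ group means (treated over control); the
#' test is a two-sided two-sample Student's t-test on log2(NRQ)
#' (equal-variance by default, matching the multiplicative error model; set
#' `var_equal = FALSE` for the Welch form).
#'
#' @param nrq Sample x gene NRQ matrix (targets in columns).
#' @param groups Named group vector (`"control"`/`"treated"`, >= 2 samples
#'   each).
#' @param targets Genes to test (default: all columns).
#' @param var_equal Use the pooled-variance Student form (default `TRUE`).
#' @return Data frame with `gene`, `fold_change`, `log2_fc`, `p_value`,
#'   `flag` (`"ok"`, or `"degenerate"` when both groups have zero variance
#'   and the p-value is undefined).
#' @export
compare_groups <- function(nrq, groups, targets = colnames(nrq),
                           var_equal = TRUE) {
  stopifnot(is.matrix(nrq))
  groups <- groups[rownames(nrq)]
  ic <- which(groups == "control")
  it <- which(groups == "treated")
  if (length(ic) < 2L || length(it) < 2L) {
    stop("both groups need at least 2 samples")
  }
  rows <- lapply(targets, function(g) {
    x <- nrq[it, g]
    y <- nrq[ic, g]
    fc <- mean(x) / mean(y)
    lx <- log2(x); ly <- log2(y)
    if (stats::var(lx) == 0 && stats::var(ly) == 0) {
      p <- NA_real_
      flag <- "degenerate"
    } else {
      p <- stats::t.test(lx, ly, var.equal = var_equal)$p.value
      flag <- "ok"
    }
    data.frame(gene = g, fold_change = fc, log2_fc = log2(fc),
               p_value = p, flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end NRQ analysis of a Cq table
#'
#' Runs [relative_quantities()], [genorm_stability()] on the reference
#' candidates, [normalize_rq()] with the two chosen references, and
#' [compare_groups()] on the targets.
#'
#' @param ct A [cq_table()].
#' @param calibrator,var_equal Passed through.
#' @return List with `rq`, `stability` (geNorm output), `nf`, `nrq`,
#'   `comparison`.
#' @export
nrq_analysis <- function(ct, calibrator = "all", var_equal = TRUE) {
  rq <- relative_quantities(ct, calibrator = calibrator)
  candidates <- names(ct$role)[ct$role == "reference_candidate"]
  stab <- genorm_stability(rq, candidates)
  norm <- normalize_rq(rq, stab$chosen_refs)
  targets <- names(ct$role)[ct$role == "target"]
  cmp <- compare_groups(norm$nrq, ct$groups, targets = targets,
                        var_equal = var_equal)
  list(rq = rq, stability = stab, nf = norm$nf, nrq = norm$nrq,
       comparison = cmp)
}

#' Read a Cq table from TSV files
#'
#' Main table: samples in rows, genes in columns, first column `sample`.
#' Gene sidecar: columns `gene`, `efficiency`, `role`. Sample sidecar:
#' columns `sample`, `group`.
#'
#' @param cq_path,gene_path,sample_path File paths.
#' @return A [cq_table()].
#' @export
read_cq_tsv <- function(cq_path, gene_path, sample_path) {
  cqdf <- utils::read.delim(cq_path, comment.char = "#", check.names = FALSE)
  genes <- utils::read.delim(gene_path, comment.char = "#")
  samples <- utils::read.delim(sample_path, comment.char = "#")
  cq <- as.matrix(cqdf[, -1, drop = FALSE])
  rownames(cq) <- cqdf[[1]]
  cq_table(cq,
           groups = stats::setNames(samples$group, samples$sample),
           efficiency = stats::setNames(genes$efficiency, genes$gene),
           role = stats::setNames(genes$role, genes$gene))
}

#' Write a Cq table to TSV files
#'
#' Inverse of [read_cq_tsv()].
#'
#' @param ct A [cq_table()].
#' @param cq_path,gene_path,sample_path Output paths.
#' @param config Configuration recorded in the headers.
#' @return `cq_path`, invisibly.
#' @export
write_cq_tsv <- function(ct, cq_path, gene_path, sample_path,
                         config = pipeline_config()) {
  cqdf <- data.frame(sample = rownames(ct$cq), ct$cq, check.names = FALSE)
  write_tsv_header(cqdf, cq_path, config)
  write_tsv_header(data.frame(gene = colnames(ct$cq),
                              efficiency = unname(ct$efficiency),
                              role = unname(ct$role)), gene_path, config)
  write_tsv_header(data.frame(sample = rownames(ct$cq),
                              group = unname(ct$groups)), sample_path, config)
  invisible(cq_path)
}
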