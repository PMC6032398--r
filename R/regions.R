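# Conserved-region annotation of GH9 catalytic domains.
#
# GH9 catalytic domains carry three conserved regions. Region I contains the
# DAGD motif whose C-terminal D is the catalytic base and whose N-terminal D
# is an essential supporting residue; Region III carries the invariant
# catalytic acid E and the nucleophile-aligning D. Region II in algal enzymes
# may contain an extra four-residue insertion (PT[PTA][YSG]).

#' Locate conserved Regions I/II/III in a protein
#'
#' Matches of the three region patterns are grouped greedily left-to-right
#' into catalytic-domain (CD) occurrences: each occurrence takes the leftmost
#' unconsumed Region I match, then the leftmost Region II match after it, then
#' the leftmost Region III match after that. An occurrence is flagged
#' canonical when all three regions are present in order and the span from
#' Region I start to Region III end does not exceed `max_span`. A new CD
#' occurrence opens at the next Region I match after a completed triad, so
#' proteins with two catalytic domains yield two occurrences.
#'
#' @param record A `protein_record` or character sequence.
#' @param patterns Named list with elements `region1`, `region2`, `region3`
#'   (`prosite_pattern`s); defaults to the packaged set. The Region III
#'   pattern is a configurable stand-in (`E-x(0,12)-D`) anchored on the
#'   invariant catalytic acid and nucleophile; a missing `region3` entry is a
#'   configuration error.
#' @param max_span Maximum aa span of a canonical triad (default 450, a
#'   typical GH9 CD size).
#' @return Data frame with one row per located region: `sequence_id`, `cd`
#'   (occurrence index), `region` (`"I"/"II"/"III"`), `start`, `end`,
#'   `matched_text`, `canonical`.
#' @export
find_regions <- function(record, patterns = gh9_patterns(), max_span = 450L) {
  rec <- as_protein_record(record)
  for (nm in c("region1", "region2", "region3")) {
    if (is.null(patterns[[nm]])) {
      stop(sprintf("configuration error: pattern '%s' is missing", nm))
    }
  }
  m1 <- scan_pattern(patterns$region1, rec)
  m2 <- scan_pattern(patterns$region2, rec)
  m3 <- scan_pattern(patterns$region3, rec)

  empty <- data.frame(sequence_id = character(0), cd = integer(0),
                      region = character(0), start = integer(0), end = integer(0),
                      matched_text = character(0), canonical = logical(0),
                      stringsAsFactors = FALSE)
  rows <- list()
  cd <- 0L
  cursor <- 0L
  repeat {
    i1 <- which(m1$start > cursor)
    if (!length(i1)) break
    r1 <- m1[i1[1], ]
    cd <- cd + 1L
    r2 <- r3 <- NULL
    i2 <- which(m2$start > r1$end)
    if (length(i2)) {
      r2 <- m2[i2[1], ]
      i3 <- which(m3$start > r2$end)
      if (length(i3)) r3 <- m3[i3[1], ]
    }
    canonical <- !is.null(r2) && !is.null(r3) &&
      (r3$end - r1$start + 1L) <= max_span
    add <- function(r, label) {
      data.frame(sequence_id = rec$id, cd = cd, region = label,
                 start = r$start, end = r$end, matched_text = r$matched_text,
                 canonical = canonical, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add(r1, "I")
    if (!is.null(r2)) rows[[length(rows) + 1L]] <- add(r2, "II")
    if (!is.null(r3)) rows[[length(rows) + 1L]] <- add(r3, "III")
    cursor <- max(r1$end, if (!is.null(r2)) r2$end else 0L,
                  if (!is.null(r3)) r3$end else 0L)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Catalytic-residue roles within a region annotation
#'
#' Region I: the N-terminal D of the DAGD motif (pattern element 7) is the
#' essential supporting residue; element 10 is the catalytic base when it is a
#' D, and is flagged `non_canonical_base` otherwise (as for the N replacing it
#' in some angiosperm enzymes). Region III: the anchoring E is the catalytic
#' acid and the downstream D the nucleophile-aligning residue. Region II has
#' no catalytic roles and yields an empty frame.
#'
#' @param region One row of the [find_regions()] output.
#' @param record The annotated `protein_record` (or sequence).
#' @return Data frame with columns `role`, `position` (1-based sequence
#'   coordinate), `residue`; residues always equal the sequence letters at the
#'   reported coordinates.
#' @export
catalytic_residues <- function(region, record) {
  rec <- as_protein_record(record)
  stopifnot(is.data.frame(region), nrow(region) == 1L)
  empty <- data.frame(role = character(0), position = integer(0),
                      residue = character(0), stringsAsFactors = FALSE)
  at <- function(pos) substring(rec$seq, pos, pos)
  if (region$region == "I") {
    # the packaged Region I pattern is fixed-length: element k sits at offset k-1
    support_pos <- region$start + 6L
    base_pos <- region$start + 9L
    base_res <- at(base_pos)
    data.frame(
      role = c("support", if (base_res == "D") "base" else "non_canonical_base"),
      position = c(support_pos, base_pos),
      residue = c(at(support_pos), base_res),
      stringsAsFactors = FALSE
    )
  } else if (region$region == "III") {
    data.frame(
      role = c("acid", "nucleophile"),
      position = c(region$start, region$end),
      residue = c(at(region$start), at(region$end)),
      stringsAsFactors = FALSE
    )
  } else {
    empty
  }
}

#' Detect the algal-specific Region II insertion
#'
#' Searches the Region II span, extended by `flank` residues on each side, for
#' the leftmost match of the four-residue insertion pattern `P-T-[PTA]-[YSG]`
#' found in algal GH9 Region II.
#'
#' @param region2 One Region II row of the [find_regions()] output.
#' @param record The annotated `protein_record` (or sequence).
#' @param flank Extension (aa) on each side of the Region II span.
#' @param pattern Insertion pattern; defaults to the packaged one.
#' @return One-row match data frame in sequence coordinates, or `NULL` when
#'   absent.
#' @export
detect_insertion <- function(region2, record, flank = 6L,
                             pattern = gh9_patterns()$insertion) {
  rec <- as_protein_record(record)
  stopifnot(is.data.frame(region2), nrow(region2) == 1L, region2$region == "II")
  lo <- max(1L, region2$start - flank)
  hi <- min(nchar(rec$seq), region2$end + flank)
  window <- substring(rec$seq, lo, hi)
  hits <- scan_pattern(pattern, window, sequence_id = rec$id)
  if (!nrow(hits)) return(NULL)
  hit <- hits[1, ]
  hit$start <- hit$start + lo - 1L
  hit$end <- hit$end + lo - 1L
  hit
}

#' Per-column residue variation profile of an alignment
#'
#' For each alignment column, the fraction of each residue (denominator: all
#' sequences, so residue fractions plus the gap fraction sum to one), residues
#' ordered by descending fraction with alphabetical tie-break.
#'
#' @param alignment Character vector of equal-length aligned sequences (gap
#'   character `-`), or a list of `protein_record`s.
#' @param column_range Optional integer range of columns to profile.
#' @return Object of class `variation_profile`: list with `columns` (each a
#'   list with `freq`, a named fraction vector, and `gap`) and `n_sequences`.
#' @export
variation_profile <- function(alignment, column_range = NULL) {
  seqs <- record_seqs(alignment)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequences have unequal lengths")
  }
  width <- lens[1]
  if (is.null(column_range)) column_range <- seq_len(width)
  if (any(column_range < 1L | column_range > width)) {
    stop("column_range out of bounds")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  cols <- lapply(column_range, function(j) {
    col <- mat[, j]
    gap <- mean(col == "-")
    res <- col[col != "-"]
    if (length(res)) {
      tab <- table(res) / length(col)
      freq <- as.numeric(tab)
      names(freq) <- names(tab)
      freq <- freq[order(-freq, names(freq))]
    } else {
      freq <- numeric(0)
    }
    list(freq = freq, gap = gap)
  })
  structure(list(columns = cols, n_sequences = length(seqs),
                 column_range = column_range),
            class = "variation_profile")
}

#' Consensus string of a variation profile
#'
#' Per column: the top residue when its fraction reaches `threshold`,
#' otherwise `x`; columns with a gap majority render as `-`.
#'
#' @param profile A [variation_profile()].
#' @param threshold Fraction in (0, 1].
#' @return Character scalar.
#' @export
consensus_string <- function(profile, threshold = 0.5) {
  stopifnot(inherits(profile, "variation_profile"),
            threshold > 0, threshold <= 1)
  out <- vapply(profile$columns, function(col) {
    if (col$gap > 0.5) return("-")
    if (length(col$freq) && col$freq[1] >= threshold) return(names(col$freq)[1])
    "x"
  }, character(1))
  paste0(out, collapse = "")
}

#' Region annotations as a GFF-like protein-coordinate table
#'
#' @param regions Output of [find_regions()] (possibly row-bound over records).
#' @param records Named list of `protein_record`s (for role attributes).
#' @return Data frame with columns `seqid`, `source`, `type`, `start`, `end`,
#'   `score`, `attributes` (1-based inclusive protein coordinates).
#' @export
regions_to_gff <- function(regions, records) {
  if (is.null(regions) || !nrow(regions)) {
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0), end = integer(0),
                      score = character(0), attributes = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    rec <- records[[r$sequence_id]]
    roles <- catalytic_residues(r, rec)
    attr_str <- sprintf("cd=%d;canonical=%s", r$cd, tolower(as.character(r$canonical)))
    if (nrow(roles)) {
      attr_str <- paste0(attr_str, ";roles=",
                         paste(sprintf("%s:%d:%s", roles$role, roles$position,
                                       roles$residue), collapse = ","))
    }
    if (r$region == "II") {
      ins <- detect_insertion(r, rec)
      if (!is.null(ins)) {
        attr_str <- paste0(attr_str, sprintf(";insertion=%d-%d", ins$start, ins$end))
      }
    }
    data.frame(seqid = r$sequence_id, source = "cellumod",
               type = paste0("region_", c(I = "I", II = "II", III = "III")[r$region]),
               start = r$start, end = r$end, score = ".",
               attributes = attr_str, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
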