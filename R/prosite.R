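# PROSITE pattern language: parsing, canonical rendering, and sequence scanning.
#
# Supported syntax: hyphen-separated elements; single residues (D), residue
# classes ([LVS]), negated classes ({P}), the any-residue wildcard x/X, repeat
# counts (n) and ranges (n,m), and the N-/C-terminal anchors '<' and '>'.
# The subscript dialect used in printed motif tables ("X_5-7_", with either a
# hyphen or an en dash inside the subscript) is normalized to x(5,7) at parse
# time. Elements in that dialect may be concatenated without hyphens.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, the only letters accepted in
#' pattern residue classes and (plus `X` for unknown residues) in sequences.
#'
#' @return Character vector of 20 one-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

new_pattern_element <- function(kind, residues, min_rep, max_rep) {
  list(kind = kind, residues = residues,
       min_rep = as.integer(min_rep), max_rep = as.integer(max_rep))
}

#' Parse a PROSITE-syntax pattern
#'
#' Turns a PROSITE pattern string into a structured `prosite_pattern` object:
#' an ordered list of elements, each a residue class, negated class or
#' any-residue wildcard with a repeat range, plus optional terminal anchors.
#'
#' @param text Pattern in PROSITE syntax (case-insensitive). Both the
#'   hyphen-separated dialect (`"[LVS]-x-[GK]-G"`) and the subscript dialect
#'   (`"[CG]X_5-7_[C]"`) are accepted.
#' @param pattern_id Short label attached to the pattern and to its matches.
#' @return An object of class `prosite_pattern` with fields `pattern_id`,
#'   `elements`, `n_anchor`, `c_anchor`.
#' @examples
#' p <- parse_prosite("[LVS]-x-[GK]-G", "demo")
#' length(p$elements)
#' @export
parse_prosite <- function(text, pattern_id = "pattern") {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("[[:space:]]+", "", text)
  txt <- sub("\\.$", "", txt)
  # normalize the subscript dialect (en dash U+2013 or hyphen inside "_n-m_")
  txt <- gsub("([xX])_([0-9]+)[–-]([0-9]+)_", "\\1(\\2,\\3)", txt)
  txt <- gsub("([xX])_([0-9]+)_", "\\1(\\2)", txt)
  if (!nzchar(txt)) stop("empty pattern text")

  n_anchor <- startsWith(txt, "<")
  if (n_anchor) txt <- substring(txt, 2L)
  c_anchor <- endsWith(txt, ">")
  if (c_anchor) txt <- substring(txt, 1L, nchar(txt) - 1L)
  if (!nzchar(txt)) stop("pattern has anchors but no elements")

  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  elements <- list()
  expect_element <- TRUE

  check_residues <- function(letters, token) {
    bad <- setdiff(letters, aa_alphabet())
    if (length(bad)) {
      stop(sprintf("unknown residue letter '%s' in token '%s'",
                   paste(bad, collapse = "', '"), token))
    }
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "-") {
      if (expect_element) stop("dangling hyphen in pattern")
      i <- i + 1L
      expect_element <- TRUE
      next
    }
    # parse one element body
    if (ch == "[" || ch == "{") {
      close <- if (ch == "[") "]" else "}"
      j <- i + 1L
      while (j <= n && chars[j] != close) j <- j + 1L
      if (j > n) stop(sprintf("unterminated '%s' class in pattern", ch))
      body <- toupper(chars[(i + 1L):(j - 1L)])
      body <- body[body != ""]
      token <- paste0(chars[i:j], collapse = "")
      if (j == i + 1L) stop(sprintf("empty class '%s'", token))
      check_residues(body, token)
      residues <- sort(unique(body))
      if (ch == "{" && length(residues) >= length(aa_alphabet())) {
        stop("negated class excludes the whole alphabet")
      }
      kind <- if (ch == "[") "class" else "negated_class"
      el <- new_pattern_element(kind, residues, 1L, 1L)
      i <- j + 1L
    } else if (toupper(ch) == "X") {
      el <- new_pattern_element("any", character(0), 1L, 1L)
      i <- i + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      up <- toupper(ch)
      check_residues(up, ch)
      el <- new_pattern_element("class", up, 1L, 1L)
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' in pattern", ch))
    }
    # optional repeat specification "(n)" or "(n,m)"
    if (i <= n && chars[i] == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) stop("unterminated repeat specification")
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]+(,[0-9]+)?$", body)) {
        stop(sprintf("malformed repeat specification '(%s)'", body))
      }
      parts <- as.integer(strsplit(body, ",", fixed = TRUE)[[1]])
      el$min_rep <- parts[1]
      el$max_rep <- parts[length(parts)]
      i <- j + 1L
    }
    if (el$min_rep > el$max_rep) {
      stop(sprintf("min repeat %d exceeds max repeat %d", el$min_rep, el$max_rep))
    }
    # a zero-length minimum is only meaningful for wildcards
    if (el$kind != "any" && el$min_rep < 1L) {
      stop("residue-class elements require a repeat count of at least 1")
    }
    elements[[length(elements) + 1L]] <- el
    expect_element <- FALSE
  }
  if (expect_element) stop("dangling hyphen in pattern")
  if (!length(elements)) stop("pattern has no elements")

  structure(
    list(pattern_id = pattern_id, elements = elements,
         n_anchor = n_anchor, c_anchor = c_anchor),
    class = "prosite_pattern"
  )
}

#' Render a pattern back to canonical PROSITE text
#'
#' The canonical form uses hyphen-separated elements, `x` for the wildcard,
#' bracketed classes with residues in alphabetical order, and `(n)`/`(n,m)`
#' repeats. `parse_prosite(prosite_canonical(p))` reproduces `p`'s elements.
#'
#' @param pattern A `prosite_pattern`.
#' @return A single string.
#' @export
prosite_canonical <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  toks <- vapply(pattern$elements, function(el) {
    body <- switch(el$kind,
      any = "x",
      class = if (length(el$residues) == 1L) el$residues
              else paste0("[", paste0(el$residues, collapse = ""), "]"),
      negated_class = paste0("{", paste0(el$residues, collapse = ""), "}")
    )
    rep <- if (el$min_rep == 1L && el$max_rep == 1L) ""
           else if (el$min_rep == el$max_rep) sprintf("(%d)", el$min_rep)
           else sprintf("(%d,%d)", el$min_rep, el$max_rep)
    paste0(body, rep)
  }, character(1))
  paste0(if (pattern$n_anchor) "<" else "",
         paste0(toks, collapse = "-"),
         if (pattern$c_anchor) ">" else "")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  sb <- span_bounds(x)
  cat(sprintf("<prosite_pattern> %s: %s  [span %d-%d]\n",
              x$pattern_id, prosite_canonical(x), sb[1], sb[2]))
  invisible(x)
}

#' Minimum and maximum match length of a pattern
#'
#' @param pattern A `prosite_pattern`.
#' @return Integer vector `c(min_len, max_len)`; every match reported by
#'   [scan_pattern()] has a length inside this interval.
#' @export
span_bounds <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  mins <- vapply(pattern$elements, function(el) el$min_rep, integer(1))
  maxs <- vapply(pattern$elements, function(el) el$max_rep, integer(1))
  c(min_len = sum(mins), max_len = sum(maxs))
}

# logical vector: does the residue at each position satisfy the element?
# An 'X' in the subject is treated as unknown: it satisfies wildcards and
# residue classes but never a negated class.
element_ok <- function(el, chars) {
  switch(el$kind,
    any = rep(TRUE, length(chars)),
    class = chars %in% el$residues | chars == "X",
    negated_class = !(chars %in% el$residues) & chars != "X"
  )
}

#' Scan a protein sequence for all matches of a pattern
#'
#' Reports every distinct `(start, end)` pair at which the pattern matches the
#' sequence exactly, honoring terminal anchors. Variable-length wildcards can
#' produce several valid ends from one start; all distinct pairs are reported
#' (the full set is needed downstream when picking region loci), deduplicated
#' and sorted by start then end. Coordinates are 1-based inclusive.
#'
#' @param pattern A `prosite_pattern`.
#' @param record A `protein_record`, or a plain character sequence
#'   (case-insensitive; `X` allowed as unknown residue).
#' @param sequence_id Identifier used in the output when `record` is a bare
#'   string.
#' @return A data frame with columns `pattern_id`, `sequence_id`, `start`,
#'   `end`, `matched_text`; zero rows when there is no match (an empty
#'   sequence yields zero rows, not an error).
#' @examples
#' p <- parse_prosite("D-x(1,2)-G", "demo")
#' scan_pattern(p, "ADAGD")
#' @export
scan_pattern <- function(pattern, record, sequence_id = "seq") {
  stopifnot(inherits(pattern, "prosite_pattern"))
  rec <- as_protein_record(record, id = sequence_id)
  seqc <- rec$seq
  empty <- data.frame(pattern_id = character(0), sequence_id = character(0),
                      start = integer(0), end = integer(0),
                      matched_text = character(0), stringsAsFactors = FALSE)
  n <- nchar(seqc)
  if (n == 0L) return(empty)
  chars <- strsplit(seqc, "", fixed = TRUE)[[1]]
  els <- pattern$elements

  # per element: length of the longest satisfying run starting at each position
  runs <- lapply(els, function(el) {
    ok <- element_ok(el, chars)
    r <- integer(n)
    acc <- 0L
    for (i in n:1L) {
      acc <- if (ok[i]) acc + 1L else 0L
      r[i] <- acc
    }
    r
  })

  starts <- if (pattern$n_anchor) 1L else seq_len(n)
  hits_s <- integer(0)
  hits_e <- integer(0)
  for (s in starts) {
    pos <- s  # set of next-unconsumed positions (values in 1..n+1)
    for (k in seq_along(els)) {
      el <- els[[k]]
      run <- runs[[k]]
      new <- integer(0)
      for (p in pos) {
        avail <- if (p > n) 0L else run[p]
        hi <- min(el$max_rep, avail)
        if (hi >= el$min_rep) new <- c(new, p + el$min_rep:hi)
      }
      pos <- unique(new)
      if (!length(pos)) break
    }
    if (length(pos)) {
      ends <- pos - 1L
      ends <- ends[ends >= s]  # matches must consume at least one residue
      if (pattern$c_anchor) ends <- ends[ends == n]
      if (length(ends)) {
        hits_s <- c(hits_s, rep(s, length(ends)))
        hits_e <- c(hits_e, ends)
      }
    }
  }
  if (!length(hits_s)) return(empty)
  ord <- order(hits_s, hits_e)
  hits_s <- hits_s[ord]
  hits_e <- hits_e[ord]
  keep <- !duplicated(paste(hits_s, hits_e))
  hits_s <- hits_s[keep]
  hits_e <- hits_e[keep]
  data.frame(
    pattern_id = pattern$pattern_id,
    sequence_id = rec$id,
    start = hits_s,
    end = hits_e,
    matched_text = substring(seqc, hits_s, hits_e),
    stringsAsFactors = FALSE
  )
}

#' Read a pattern file
#'
#' One pattern per line: `ID<TAB>PROSITE-text`. Blank lines and lines starting
#' with `#` are skipped.
#'
#' @param path Path to the file.
#' @return Named list of `prosite_pattern` objects.
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  pats <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop(sprintf("malformed pattern line: '%s'", ln))
    parse_prosite(parts[2], pattern_id = parts[1])
  })
  names(pats) <- vapply(pats, function(p) p$pattern_id, character(1))
  pats
}

#' Packaged GH9 pattern set
#'
#' The default pattern set shipped with the package: `region1` (the Region I
#' pattern, PROSITE PS60032), `region2` (the revised PS00592 Region II
#' pattern), `insertion` (the algal-specific four-residue Region II insertion
#' `P-T-[PTA]-[YSG]`), `region3` (a configurable stand-in anchored on the
#' invariant catalytic acid E and downstream nucleophile D; no community
#' pattern exists for Region III) and `hevein` (the CBM18 Hevein cysteine
#' motif).
#'
#' @return Named list of `prosite_pattern` objects.
#' @export
gh9_patterns <- function() {
  path <- system.file("extdata", "gh9_patterns.tsv", package = "cellumod")
  if (!nzchar(path)) stop("packaged pattern file not found")
  read_pattern_file(path)
}
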