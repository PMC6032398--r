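# Records, FASTA input/output, pipeline configuration and the one-call pipeline.

#' Create a protein record
#'
#' A minimal container for an identified amino-acid sequence, optionally
#' carrying a ground-truth segment map (synthetic proteins emitted by the
#' generator keep their true segmentation here).
#'
#' @param id Sequence identifier.
#' @param seq Amino-acid sequence (upper-cased on ingest; `X` allowed).
#' @param truth Optional data frame of ground-truth segments.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, seq, truth = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  structure(list(id = id, seq = seq, truth = truth), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$seq),
              if (!is.null(x$truth)) sprintf(", %d truth segments", nrow(x$truth)) else ""))
  invisible(x)
}

#' Coerce to a protein record
#'
#' @param x A `protein_record` or a single character sequence.
#' @param id Identifier used when `x` is a bare string.
#' @return A `protein_record`.
#' @export
as_protein_record <- function(x, id = "seq") {
  if (inherits(x, "protein_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(protein_record(id, x))
  stop("cannot coerce to protein_record")
}

validate_protein_letters <- function(seqs, ids, aligned = FALSE) {
  allowed <- c(aa_alphabet(), "X", if (aligned) "-")
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% allowed))
    if (length(bad)) {
      stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                   chars[bad[1]], bad[1], ids[i]))
    }
  }
  invisible(TRUE)
}

#' Read protein sequences from FASTA
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are upper-cased. Letters outside the 20 standard amino acids plus
#' `X` (and `-` when `aligned = TRUE`) and duplicated identifiers are rejected
#' with a named error.
#'
#' @param path FASTA file path (wrapped or unwrapped lines).
#' @param aligned Accept gap characters (`-`) when `TRUE`.
#' @return Named list of `protein_record` objects.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop(sprintf("ingest: no sequences found in '%s'", path))
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("ingest: duplicate sequence id '%s'", ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(set))
  validate_protein_letters(seqs, ids, aligned = aligned)
  recs <- Map(protein_record, ids, seqs)
  names(recs) <- ids
  recs
}

#' Write protein records to FASTA
#'
#' @param records Named list of `protein_record`s (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly. Output is byte-stable for identical input.
#' @export
write_fasta <- function(records, path, width = 70L) {
  seqs <- record_seqs(records)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# named character vector of sequences from a list of records / character vector
record_seqs <- function(records) {
  if (is.character(records)) {
    if (is.null(names(records))) names(records) <- paste0("seq", seq_along(records))
    return(toupper(records))
  }
  if (inherits(records, "protein_record")) records <- list(records)
  out <- vapply(records, function(r) as_protein_record(r)$seq, character(1))
  ids <- vapply(records, function(r) as_protein_record(r)$id, character(1))
  names(out) <- ids
  out
}

#' Pipeline configuration
#'
#' All tunable thresholds of the analysis in one flat list; every output file
#' written by [run_pipeline()] carries the configuration hash in its comment
#' header so that threshold-sensitive results are reproducible.
#'
#' @param ... Overrides of the defaults, as `name = value` pairs.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # region annotation
    max_triad_span = 450L,     # max aa from Region I start to Region III end
    insertion_flank = 6L,      # aa searched either side of Region II
    # catalytic-domain padding around the region triad
    cd_pad_left = 30L,
    cd_pad_right = 60L,
    # linker classification
    min_linker_len = 8L,
    max_linker_len = 50L,
    ps_rich_min = 0.40, ps_rich_max_t = 0.10, pst_rich_min = 0.45, pst_min_t = 0.10,
    # CBM detection
    cbm_min_len = 50L, cbm_max_len = 130L,
    cbm_min_cys = 8L, cbm_min_cys_frac = 0.08,
    cbm_max_c_gap = 20L, cbm_pad = 3L,
    # architecture rendering
    unknown_render_min = 10L,
    # alignment / identity
    substitution_matrix = "BLOSUM62",
    gap_open = 10, gap_ext = 0.5,
    identity_denom = "shorter",
    distance_transform = "linear",  # d = 100 - identity; "poisson" available
    # trees
    n_bootstrap = 100L,
    # qPCR
    calibrator = "all",
    var_equal = TRUE,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown configuration field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Hash a configuration
#'
#' Stable MD5 of the deparsed configuration, used in output headers.
#' @param config A `pipeline_config`.
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(config) {
  c(sprintf("# cellumod %s", as.character(utils::packageVersion("cellumod"))),
    sprintf("# config_hash=%s", config_hash(config)))
}

#' Write a TSV with a tool/config comment header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config A `pipeline_config` recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_header <- function(df, path, config = pipeline_config()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full annotation pipeline
#'
#' Executes pattern scanning, region annotation, segmentation and architecture
#' classification on a set of proteins, then (given at least two or three
#' sequences) the percent-identity matrix and the neighbor-joining tree.
#' Any stage failure aborts with an error naming the stage.
#'
#' @param records Named list of `protein_record`s, or a FASTA path.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `regions.tsv`, `architecture.tsv`, `identity.tsv`, `groups.tsv` and
#'   `tree.nwk` (all with config-hash headers; outputs are deterministic
#'   functions of inputs + configuration).
#' @param groups Optional named character vector of group tags (for the
#'   identity/tree stage).
#' @param patterns Pattern set; defaults to [gh9_patterns()].
#' @return A list with elements `regions`, `architectures`, `identity`,
#'   `tree` (the latter two `NULL` when too few sequences).
#' @export
run_pipeline <- function(records, config = pipeline_config(), out_dir = NULL,
                         groups = NULL, patterns = gh9_patterns()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  records <- stage("ingest", {
    if (is.character(records) && length(records) == 1L && file.exists(records)) {
      read_fasta(records)
    } else {
      recs <- lapply(records, as_protein_record)
      if (!length(recs)) stop("no input sequences")
      names(recs) <- vapply(recs, function(r) r$id, character(1))
      recs
    }
  })

  regions <- stage("region_annotation", {
    do.call(rbind, lapply(records, function(r) {
      find_regions(r, patterns = patterns, max_span = config$max_triad_span)
    }))
  })

  archs <- stage("segmentation", {
    lapply(records, function(r) {
      annotate_architecture(
        r, regions = regions[regions$sequence_id == r$id, , drop = FALSE],
        config = config, patterns = patterns)
    })
  })

  identity <- NULL
  tree <- NULL
  if (length(records) >= 2L) {
    identity <- stage("identity", {
      identity_matrix(records, groups = groups,
                      substitution_matrix = config$substitution_matrix,
                      gap_open = config$gap_open, gap_ext = config$gap_ext,
                      identity_denom = config$identity_denom)
    })
  }
  if (length(records) >= 3L) {
    tree <- stage("tree", nj_tree(identity, distance_transform = config$distance_transform))
  }

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv_header(regions_to_gff(regions, records),
                       file.path(out_dir, "regions.tsv"), config)
      write_tsv_header(architecture_table(archs),
                       file.path(out_dir, "architecture.tsv"), config)
      if (!is.null(identity)) {
        imat <- as.data.frame(identity$values)
        imat <- cbind(id = identity$labels, imat)
        write_tsv_header(imat, file.path(out_dir, "identity.tsv"), config)
        if (!is.null(identity$groups)) {
          write_tsv_header(
            data.frame(id = names(identity$groups), group = unname(identity$groups)),
            file.path(out_dir, "groups.tsv"), config)
        }
      }
      if (!is.null(tree)) {
        con <- file(file.path(out_dir, "tree.nwk"), open = "wt")
        writeLines(output_header(config), con)
        close(con)
        ape::write.tree(tree, file.path(out_dir, "tree.nwk"), append = TRUE)
      }
    })
  }
  list(records = records, regions = regions, architectures = archs,
       identity = identity, tree = tree)
}
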