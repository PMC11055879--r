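#' @importFrom utils read.delim write.table head
#' @importFrom stats sd density median setNames lm coef
#' @importFrom stats rnorm rlnorm rnbinom runif
NULL

#' Recognised construct classes
#'
#' Construct classes used throughout the package. `single_with_control_first`
#' corresponds to N_gene constructs (control guide in the first position),
#' `single_with_control_second` to gene_N constructs, `pair` to A_B
#' constructs targeting two genes, `control` to constructs targeting only
#' control labels, and `seven_mer` to 7-guide essential/non-essential
#' titration arrays.
#'
#' @export
construct_classes <- function() {
  c("single_with_control_first", "single_with_control_second",
    "pair", "triple", "quad", "control", "seven_mer")
}

split_targets <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

join_targets <- function(x) vapply(x, paste, "", collapse = ";")

#' Validate a construct manifest
#'
#' Checks the invariants a manifest must satisfy: unique construct ids,
#' non-empty target lists, recognised classes, and equal spacer lengths
#' (20 or 23 nt) within each record when spacers are present.
#'
#' @param manifest data.frame with columns `construct_id`, `targets`
#'   (semicolon-joined), `class`, `study_id`, `cell_line` and optionally
#'   `spacers` (semicolon-joined).
#' @return The manifest, invisibly, after validation.
#' @export
validate_manifest <- function(manifest) {
  required <- c("construct_id", "targets", "class", "study_id", "cell_line")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0)
    stop("manifest is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  dup <- manifest$construct_id[duplicated(manifest$construct_id)]
  if (length(dup) > 0)
    stop("duplicated construct_id in manifest: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  tl <- lengths(split_targets(manifest$targets))
  if (any(tl == 0) || any(!nzchar(manifest$targets)))
    stop("manifest rows with empty targets: ",
         paste(manifest$construct_id[tl == 0 | !nzchar(manifest$targets)],
               collapse = ", "), call. = FALSE)
  bad_class <- setdiff(unique(manifest$class), construct_classes())
  if (length(bad_class) > 0)
    stop("unrecognised construct class: ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  if ("spacers" %in% names(manifest)) {
    has <- !is.na(manifest$spacers) & nzchar(manifest$spacers)
    if (any(has)) {
      sp <- split_targets(manifest$spacers[has])
      ok <- vapply(sp, function(s) {
        n <- nchar(s)
        length(unique(n)) == 1 && n[1] %in% c(20L, 23L)
      }, logical(1))
      if (any(!ok))
        stop("spacer lengths must all be equal within a record (20 or 23 nt); ",
             "offending constructs: ",
             paste(manifest$construct_id[has][!ok], collapse = ", "),
             call. = FALSE)
    }
  }
  invisible(manifest)
}

#' Read a construct manifest TSV
#'
#' @param path Path to a TSV with columns `construct_id`, `targets`
#'   (semicolon-joined), `class`, `study_id`, `cell_line` and optionally
#'   `spacers`.
#' @return A validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_manifest(m)
  m
}

#' Build a count matrix container
#'
#' Bundles a construct x sample integer count table with its construct
#' manifest and sample metadata.
#'
#' @param counts Numeric matrix, constructs x samples, non-negative;
#'   rownames are construct ids, colnames sample ids.
#' @param manifest Construct manifest (see [validate_manifest()]).
#' @param samples data.frame with columns `sample_id`, `role` (`reference`
#'   or `endpoint`), `replicate` (integer), `timepoint` (label).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, manifest, samples) {
  validate_manifest(manifest)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have construct ids as rownames", call. = FALSE)
  if (!setequal(rownames(counts), manifest$construct_id) ||
      nrow(counts) != nrow(manifest))
    stop("counts rows do not match manifest construct ids; unmatched: ",
         paste(setdiff(rownames(counts), manifest$construct_id),
               collapse = ", "), call. = FALSE)
  if (!all(c("sample_id", "role", "replicate", "timepoint") %in%
             names(samples)))
    stop("samples needs columns sample_id, role, replicate, timepoint",
         call. = FALSE)
  if (!setequal(colnames(counts), samples$sample_id) ||
      ncol(counts) != nrow(samples))
    stop("counts columns do not match samples$sample_id", call. = FALSE)
  if (!any(samples$role == "reference"))
    stop("at least one reference sample is required", call. = FALSE)
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts must be non-negative and complete", call. = FALSE)
  counts <- counts[manifest$construct_id, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, manifest = manifest, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "constructs x",
      ncol(x$counts), "samples\n")
  cat("  reference samples:",
      paste(x$samples$sample_id[x$samples$role == "reference"],
            collapse = ", "), "\n")
  invisible(x)
}

infer_sample_metadata <- function(sample_ids) {
  is_ref <- grepl("^(t0|plasmid|ref)", sample_ids, ignore.case = TRUE)
  rep_idx <- suppressWarnings(
    as.integer(sub(".*[._-]r(?:ep)?([0-9]+)$", "\\1", sample_ids,
                   perl = TRUE)))
  rep_idx[is.na(rep_idx)] <- 1L
  data.frame(sample_id = sample_ids,
             role = ifelse(is_ref, "reference", "endpoint"),
             replicate = rep_idx,
             timepoint = sub("[._-]r(?:ep)?[0-9]+$", "", sample_ids,
                             perl = TRUE),
             stringsAsFactors = FALSE)
}

#' Read a construct count table
#'
#' Reads a TSV whose first column is `construct_id` and whose remaining
#' columns are per-sample read counts, validates it against a manifest,
#' and returns a [count_matrix()]. Sample roles default to inference from
#' sample ids (ids starting with `T0`, `plasmid` or `ref` are reference
#' samples); pass `samples` to state them explicitly.
#'
#' @param path Path to the count TSV.
#' @param manifest Manifest data.frame or path to a manifest TSV.
#' @param samples Optional sample metadata data.frame (see [count_matrix()]).
#' @return A `count_matrix`.
#' @export
read_count_table <- function(path, manifest, samples = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "construct_id")
    stop("count table must have construct_id as its first column",
         call. = FALSE)
  if (anyDuplicated(tab$construct_id))
    stop("duplicated construct_id in count table: ",
         paste(unique(tab$construct_id[duplicated(tab$construct_id)]),
               collapse = ", "), call. = FALSE)
  unmatched <- setdiff(tab$construct_id, manifest$construct_id)
  if (length(unmatched) > 0)
    stop("construct ids absent from manifest: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$construct_id
  storage.mode(counts) <- "double"
  if (is.null(samples)) samples <- infer_sample_metadata(colnames(counts))
  keep <- manifest$construct_id %in% rownames(counts)
  count_matrix(counts, manifest[keep, , drop = FALSE], samples)
}

#' Write a construct count table
#'
#' @param cm A `count_matrix`.
#' @param path Output TSV path.
#' @export
write_count_table <- function(cm, path) {
  out <- data.frame(construct_id = rownames(cm$counts),
                    cm$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Specification of the exactly-matched region of a guide-array amplicon
#'
#' The matched region is the concatenation of all spacers and the internal
#' direct repeats (DRs) between them; the leading DR is carried on the
#' vector backbone and excluded from matching.
#'
#' @param n_spacers Number of spacers on the array.
#' @param spacer_length Spacer length in nt.
#' @param dr_length Direct-repeat length in nt.
#' @param leading_dr_excluded Whether the leading DR is outside the
#'   matched region (it is for the vectors supported here).
#' @return A `match_spec` list with the derived `matched_region_length`.
#' @examples
#' seven_mer_match_spec()$matched_region_length  # 281
#' @export
match_spec <- function(n_spacers, spacer_length, dr_length,
                       leading_dr_excluded = TRUE) {
  stopifnot(n_spacers >= 1, spacer_length > 0, dr_length >= 0)
  structure(list(
    n_spacers = as.integer(n_spacers),
    spacer_length = as.integer(spacer_length),
    dr_length = as.integer(dr_length),
    leading_dr_excluded = isTRUE(leading_dr_excluded),
    matched_region_length =
      as.integer(n_spacers * spacer_length + (n_spacers - 1) * dr_length)),
    class = "match_spec")
}

#' @rdname match_spec
#' @export
seven_mer_match_spec <- function() match_spec(7L, 23L, 20L)

#' @rdname match_spec
#' @export
in4mer_match_spec <- function() match_spec(4L, 20L, 20L)

#' Count reads by exact matching against a guide-array library
#'
#' A read increments a construct's count iff the construct's full matched
#' region occurs verbatim as a substring of the read; no partial or
#' mismatched credit is given. A read whose sequence contains the matched
#' region of more than one library construct (possible only with
#' pathological libraries) is credited to none; the number of such reads
#' is returned in the `multi_matched` attribute. Reads are scanned on the
#' given strand only unless `scan_reverse_complement = TRUE`.
#'
#' @param reads Character vector of read sequences (FASTQ qualities are
#'   irrelevant to identity matching; see [read_fastq_sequences()]).
#' @param library data.frame with columns `construct_id` and `sequence`
#'   (the full matched region of each array).
#' @param spec A [match_spec()]; every library sequence must have length
#'   `spec$matched_region_length`.
#' @param scan_reverse_complement Also scan the reverse complement of
#'   each read.
#' @return Named integer vector of counts, one per library construct,
#'   with attributes `n_reads` and `multi_matched`.
#' @export
count_exact_matches <- function(reads, library, spec,
                                scan_reverse_complement = FALSE) {
  stopifnot(inherits(spec, "match_spec"))
  if (!all(c("construct_id", "sequence") %in% names(library)))
    stop("library needs columns construct_id and sequence", call. = FALSE)
  len <- nchar(library$sequence)
  if (any(len != spec$matched_region_length))
    stop("library sequences of wrong length (expected ",
         spec$matched_region_length, " nt): ",
         paste(library$construct_id[len != spec$matched_region_length],
               collapse = ", "), call. = FALSE)
  reads <- as.character(reads)
  if (scan_reverse_complement && length(reads) > 0) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  } else {
    rc <- NULL
  }
  # hit matrix: reads x constructs, then drop multi-hit reads
  hits <- vapply(library$sequence, function(s) {
    h <- grepl(s, reads, fixed = TRUE)
    if (!is.null(rc)) h <- h | grepl(s, rc, fixed = TRUE)
    h
  }, logical(length(reads)))
  hits <- matrix(hits, nrow = length(reads))
  n_hits <- rowSums(hits)
  multi <- sum(n_hits > 1)
  if (multi > 0)
    warning(multi, " read(s) matched more than one library sequence; ",
            "credited to none", call. = FALSE)
  counts <- as.integer(colSums(hits[n_hits == 1, , drop = FALSE]))
  structure(setNames(counts, library$construct_id),
            n_reads = length(reads), multi_matched = multi)
}

#' Read sequences from a FASTQ file
#'
#' Plain or gzipped FASTQ; quality strings are discarded (exact-match
#' counting uses sequence identity only).
#'
#' @param path FASTQ path.
#' @return Character vector of read sequences.
#' @export
read_fastq_sequences <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Read a gene list (one symbol per line)
#'
#' @param path Text file path; blank lines and lines starting with `#`
#'   are skipped.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

lfc_columns <- function(fc) grep("^lfc\\.", names(fc), value = TRUE)

#' Write a fold-change table
#'
#' TSV with columns `construct_id`, `targets`, `class`, one `lfc.<sample>`
#' column per endpoint replicate, and `mean_lfc`. LFC values are written
#' with 6 decimal places.
#'
#' @param fc A fold-change table (see [compute_lfc()]).
#' @param path Output path.
#' @export
write_fold_change_table <- function(fc, path) {
  cols <- c("construct_id", "targets", "class", lfc_columns(fc),
            intersect("mean_lfc", names(fc)))
  out <- fc[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fold-change table written by [write_fold_change_table()]
#'
#' @param path TSV path.
#' @return Fold-change data.frame.
#' @export
read_fold_change_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
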