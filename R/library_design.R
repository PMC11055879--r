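#' Internal direct-repeat sequences used between array slots
#'
#' The three distinct 20-nt Cas12a direct repeats placed, in order,
#' between slots 1-2, 2-3 and 3-4 of a four-guide array. Sequence
#' diversity between repeats minimizes recombination during synthesis
#' and cloning.
#'
#' @return Character vector of the three internal DRs.
#' @export
internal_dr_sequences <- function() {
  c("TAATTTCTACTATTGTAGAT",
    "AAATTTCTACTCTAGTAGAT",
    "TAATTTCTACTGTCGTAGAT")
}

oligo_templates <- list(
  prototype = list(
    primer5 = "AATGATACGGCGACCACCGA",
    bsmbi5 = "cgtctcgAGAT",
    terminator = "TTTTTT",
    bsmbi3 = "GAATggagacg",
    primer3 = "ATCTCGTATGCCGTCTTCTGCTTG"),
  inzolia = list(
    primer5 = "AGGCACTTGCTCGTACGACG",
    bsmbi5 = "cgtctcgAGAT",
    terminator = "TTTTTT",
    bsmbi3 = "GAATggagacg",
    primer3 = "TTAAGGTGCCGGGCCCACAT"))

#' Library design filter profile
#'
#' Filter thresholds for paralog candidate selection. The `prototype`
#' profile applies a mean-identity band of (30, 99) percent, delta
#' identity < 10, expression mean > 2 with sd < 1.5, and a
#' difference-from-top-paralog family threshold of 10 percent. The
#' `inzolia` profile drops the identity upper bound, the delta filter and
#' the expression-variance filter, retains the mean-expression filter,
#' and expands the family threshold to 20 percent. Disabled thresholds
#' are NA.
#'
#' @param name `prototype` or `inzolia`.
#' @return A `design_profile` list.
#' @export
design_profile <- function(name = c("prototype", "inzolia")) {
  name <- match.arg(name)
  p <- switch(name,
    prototype = list(identity_min = 30, identity_max = 99,
                     delta_max = 10, expr_mean_min = 2,
                     expr_std_max = 1.5, family_drop_max = 10),
    inzolia = list(identity_min = 30, identity_max = NA_real_,
                   delta_max = NA_real_, expr_mean_min = 2,
                   expr_std_max = NA_real_, family_drop_max = 20))
  structure(c(list(name = name), p), class = "design_profile")
}

#' Derive mean and delta identity for paralog candidates
#'
#' Sequence identity between two paralogs is directional (AB and BA can
#' differ when protein lengths differ); mean identity is (AB + BA)/2 and
#' delta identity |AB - BA|.
#'
#' @param candidates data.frame with `geneA`, `geneB`, `identity_ab`,
#'   `identity_ba` (percent).
#' @return The data.frame with `mean_identity` and `delta_identity`
#'   columns added.
#' @export
paralog_candidates <- function(candidates) {
  stopifnot(all(c("geneA", "geneB", "identity_ab", "identity_ba") %in%
                  names(candidates)))
  if (any(candidates$identity_ab < 0 | candidates$identity_ab > 100 |
          candidates$identity_ba < 0 | candidates$identity_ba > 100))
    stop("identities must lie in [0, 100] percent", call. = FALSE)
  candidates$mean_identity <-
    (candidates$identity_ab + candidates$identity_ba) / 2
  candidates$delta_identity <-
    abs(candidates$identity_ab - candidates$identity_ba)
  candidates
}

#' Select paralog pairs through a design profile's filters
#'
#' A pair is accepted iff identity_min < mean identity < identity_max
#' (strict), delta identity < delta_max where enabled, both genes have
#' expression mean > expr_mean_min, and expression sd < expr_std_max
#' where enabled. Rejections are recorded with a reason, not raised.
#'
#' @param candidates Output of [paralog_candidates()].
#' @param expr data.frame with `gene`, `expr_mean`, `expr_std`.
#' @param profile A [design_profile()].
#' @return The candidates with `accepted` (logical) and `reject_reason`.
#' @export
select_pairs <- function(candidates, expr, profile = design_profile()) {
  ea <- expr[match(candidates$geneA, expr$gene), ]
  eb <- expr[match(candidates$geneB, expr$gene), ]
  reason <- rep(NA_character_, nrow(candidates))
  fail <- function(cur, cond, why) ifelse(is.na(cur) & cond, why, cur)
  reason <- fail(reason, is.na(ea$gene) | is.na(eb$gene),
                 "expression_missing")
  reason <- fail(reason, !is.na(ea$gene) & !is.na(eb$gene) &
                 !(candidates$mean_identity > profile$identity_min &
                   (is.na(profile$identity_max) |
                      candidates$mean_identity < profile$identity_max)),
                 "identity_band")
  if (!is.na(profile$delta_max))
    reason <- fail(reason,
                   !(candidates$delta_identity < profile$delta_max),
                   "delta_identity")
  reason <- fail(reason, !is.na(ea$gene) & !is.na(eb$gene) &
                 !(ea$expr_mean > profile$expr_mean_min &
                     eb$expr_mean > profile$expr_mean_min),
                 "expression_mean")
  if (!is.na(profile$expr_std_max))
    reason <- fail(reason, !is.na(ea$gene) & !is.na(eb$gene) &
                   !(ea$expr_std < profile$expr_std_max &
                       eb$expr_std < profile$expr_std_max),
                   "expression_variance")
  candidates$accepted <- is.na(reason)
  candidates$reject_reason <- reason
  candidates
}

#' Cluster paralogs into families via the difference-from-top-paralog rule
#'
#' For each gene A (the anchor), its top paralog B is the candidate with
#' maximum identity; any other candidate C joins A's family when
#' identity(A, B) - identity(A, C) < `family_drop_max` (strict).
#' Anchors are processed in sorted gene order and each gene belongs to
#' at most one family: a candidate already claimed by an earlier anchor
#' is skipped, so membership is decided by the admitting anchor's drop
#' rule, never transitively. Families larger than four are truncated to
#' the anchor plus the three smallest-drop members; leftover singletons
#' are dropped. Output is deterministic given the input.
#'
#' @param identities data.frame with `gene`, `paralog`, `identity`
#'   (percent; one row per directed gene-paralog relation).
#' @param profile A [design_profile()].
#' @return List of character vectors (families of 2-4 sorted symbols).
#' @export
cluster_families <- function(identities, profile = design_profile()) {
  stopifnot(all(c("gene", "paralog", "identity") %in% names(identities)))
  identities <- identities[order(identities$gene, identities$paralog,
                                 -identities$identity), ]
  by_gene <- split(identities, identities$gene)
  assigned <- character()
  fams <- list()
  for (g in sort(names(by_gene))) {
    if (g %in% assigned) next
    tab <- by_gene[[g]]
    tab <- tab[!(tab$paralog %in% assigned) & tab$paralog != g, ,
               drop = FALSE]
    if (nrow(tab) == 0) next
    top <- max(tab$identity)
    cand <- tab[top - tab$identity < profile$family_drop_max, ,
                drop = FALSE]
    # cap at 4 members: anchor plus the three smallest drops
    cand <- cand[order(-cand$identity, cand$paralog), , drop = FALSE]
    members <- c(g, utils::head(unique(cand$paralog), 3))
    if (length(members) < 2) next
    assigned <- c(assigned, members)
    fams[[length(fams) + 1L]] <- sort(members)
  }
  fams[order(vapply(fams, `[`, "", 1))]
}

#' Build four-guide arrays for singles and paralog families
#'
#' Every target receives two sibling arrays. Singles carry their top
#' four guides, with the second sibling in reversed slot order. Pairs
#' carry two guides per gene interleaved (A, B, A, B), again reversed in
#' the second sibling. Triples carry one guide per gene plus a pad guide
#' in slot 4; quads one guide per gene; for triples and quads the two
#' siblings use disjoint guide sets (ranks 1 and 2). Pads come from a
#' non-essential gene guide list (`nonessential_gene` policy) or
#' non-targeting sequences (`nontargeting`).
#'
#' @param singles Character vector of single-gene targets.
#' @param families List of character vectors (2-4 genes each).
#' @param guides data.frame with `gene`, `rank`, `spacer` (20-nt).
#' @param pad_policy `nonessential_gene` or `nontargeting`.
#' @param pad_guides data.frame with `gene`, `rank`, `spacer` supplying
#'   pad guides (non-essential genes or non-targeting labels).
#' @return data.frame of arrays: `array_id`, `target`, `class`,
#'   `sibling`, `slot_targets`, `spacers` (both semicolon-joined).
#' @export
build_arrays <- function(singles = character(), families = list(),
                         guides,
                         pad_policy = c("nonessential_gene",
                                        "nontargeting"),
                         pad_guides = NULL) {
  pad_policy <- match.arg(pad_policy)
  stopifnot(all(c("gene", "rank", "spacer") %in% names(guides)))
  ranked <- function(g, n) {
    tab <- guides[guides$gene == g, ]
    tab <- tab[order(tab$rank), ]
    if (nrow(tab) < n)
      stop("insufficient guides for gene ", g, " (need ", n, ", have ",
           nrow(tab), ")", call. = FALSE)
    tab$spacer[seq_len(n)]
  }
  pad_pool <- if (!is.null(pad_guides))
    pad_guides[order(pad_guides$gene, pad_guides$rank), ] else NULL
  pad_i <- 0L
  next_pad <- function() {
    if (is.null(pad_pool) || nrow(pad_pool) == 0)
      stop("triples require pad guides but none were supplied",
           call. = FALSE)
    pad_i <<- pad_i %% nrow(pad_pool) + 1L
    pad_pool[pad_i, c("gene", "spacer")]
  }
  rows <- list()
  emit <- function(target, class, sibling, slot_targets, spacers) {
    rows[[length(rows) + 1L]] <<- data.frame(
      array_id = sprintf("%s_v%d", gsub(";", "-", target), sibling),
      target = target, class = class, sibling = sibling,
      slot_targets = paste(slot_targets, collapse = ";"),
      spacers = paste(spacers, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  for (g in singles) {
    sp <- ranked(g, 4)
    emit(g, "single", 1L, rep(g, 4), sp)
    emit(g, "single", 2L, rep(g, 4), rev(sp))
  }
  for (fam in families) {
    fam <- sort(fam)
    key <- paste(fam, collapse = ";")
    if (length(fam) == 2) {
      a <- ranked(fam[1], 2); b <- ranked(fam[2], 2)
      slots <- c(fam[1], fam[2], fam[1], fam[2])
      sp <- c(a[1], b[1], a[2], b[2])
      emit(key, "pair", 1L, slots, sp)
      emit(key, "pair", 2L, rev(slots), rev(sp))
    } else if (length(fam) == 3) {
      for (v in 1:2) {
        sp <- vapply(fam, function(g) ranked(g, 2)[v], "")
        pad <- next_pad()
        emit(key, "triple", v, c(fam, pad$gene), c(sp, pad$spacer))
      }
    } else if (length(fam) == 4) {
      for (v in 1:2) {
        sp <- vapply(fam, function(g) ranked(g, 2)[v], "")
        emit(key, "quad", v, fam, sp)
      }
    } else {
      stop("family size must be 2-4: ", key, call. = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(array_id = character(), target = character(),
                      class = character(), sibling = integer(),
                      slot_targets = character(), spacers = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a synthesis oligo for a four-guide array
#'
#' Concatenates, in order: 5' amplification primer, BsmBI site with AGAT
#' overhang, spacer 1, internal DR a, spacer 2, DR b, spacer 3, DR c,
#' spacer 4, the TTTTTT Pol III terminator, the 3' BsmBI region, and the
#' 3' primer. Case follows the printed template (restriction flanks
#' lowercase) so outputs are byte-comparable. Prototype oligos are
#' 212 nt; inzolia oligos 208 nt.
#'
#' @param spacers Character vector of exactly four 20-nt ACGT spacers.
#' @param array_id Identifier carried into the record.
#' @param template `prototype` or `inzolia`.
#' @return An `oligo_record` list: `array_id`, `sequence`,
#'   `segment_map` (data.frame of labeled segments with offsets).
#' @export
assemble_oligo <- function(spacers, array_id = "array",
                           template = c("prototype", "inzolia")) {
  template <- match.arg(template)
  if (length(spacers) != 4)
    stop("exactly 4 spacers are required", call. = FALSE)
  if (any(nchar(spacers) != 20))
    stop("spacers must be exactly 20 nt", call. = FALSE)
  if (any(!grepl("^[ACGT]+$", spacers)))
    stop("spacers must be ACGT only", call. = FALSE)
  tm <- oligo_templates[[template]]
  dr <- internal_dr_sequences()
  seg <- c(primer5 = tm$primer5, restriction5 = tm$bsmbi5,
           spacer1 = spacers[1], dr_a = dr[1],
           spacer2 = spacers[2], dr_b = dr[2],
           spacer3 = spacers[3], dr_c = dr[3],
           spacer4 = spacers[4], terminator = tm$terminator,
           restriction3 = tm$bsmbi3, primer3 = tm$primer3)
  len <- nchar(seg)
  end <- cumsum(len)
  segment_map <- data.frame(segment = names(seg), sequence = unname(seg),
                            start = end - len + 1L, end = end,
                            length = len, row.names = NULL,
                            stringsAsFactors = FALSE)
  structure(list(array_id = array_id,
                 sequence = paste(seg, collapse = ""),
                 template = template,
                 segment_map = segment_map),
            class = "oligo_record")
}

#' Assemble oligos for a whole array design
#'
#' @param arrays [build_arrays()] output.
#' @param template `prototype` or `inzolia`.
#' @return data.frame `array_id`, `sequence`.
#' @export
assemble_oligos <- function(arrays, template = c("prototype", "inzolia")) {
  template <- match.arg(template)
  seqs <- vapply(seq_len(nrow(arrays)), function(i) {
    sp <- strsplit(arrays$spacers[i], ";", fixed = TRUE)[[1]]
    assemble_oligo(sp, arrays$array_id[i], template)$sequence
  }, "")
  data.frame(array_id = arrays$array_id, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write assembled oligos as FASTA
#'
#' @param oligos [assemble_oligos()] output.
#' @param path Output FASTA path.
#' @export
write_oligo_fasta <- function(oligos, path) {
  x <- Biostrings::BStringSet(setNames(oligos$sequence, oligos$array_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Account for a built array design
#'
#' Counts arrays by class, asserts uniqueness of array ids and (when
#' oligos are supplied) of assembled sequences, and reports totals.
#'
#' @param arrays [build_arrays()] output (control arrays may be included
#'   as rows with class `control`).
#' @param oligos Optional [assemble_oligos()] output for sequence
#'   collision checking.
#' @return List with `by_class` (named counts), `total`, and
#'   `paralog_family_arrays` (pairs + triples + quads).
#' @export
manifest_accounting <- function(arrays, oligos = NULL) {
  dup <- arrays$array_id[duplicated(arrays$array_id)]
  if (length(dup) > 0)
    stop("duplicate array ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (!is.null(oligos)) {
    dseq <- oligos$array_id[duplicated(oligos$sequence) |
                              duplicated(oligos$sequence, fromLast = TRUE)]
    if (length(dseq) > 0)
      stop("assembled sequence collisions between arrays: ",
           paste(dseq, collapse = ", "), call. = FALSE)
  }
  by_class <- if (nrow(arrays) == 0) integer(0) else
    table(arrays$class)
  fam <- sum(arrays$class %in% c("pair", "triple", "quad"))
  list(by_class = c(by_class), total = nrow(arrays),
       paralog_family_arrays = fam)
}

#' Expected array counts for a library specification
#'
#' Each single gene and each paralog family is targeted by two sibling
#' arrays; control arrays are counted as given. The prototype manifest
#' (19,687 singles, 2082 pairs, 167 triples, 48 quads, 4 EGFP arrays)
#' totals 43,972 arrays; the Inzolia paralog component (4435 pairs, 376
#' triples, 100 quads) totals 9822 family-targeting arrays.
#'
#' @param n_singles,n_pairs,n_triples,n_quads Target counts.
#' @param n_control_arrays Control arrays (already array-level counts).
#' @return List with `total`, `single_arrays`, `paralog_family_arrays`,
#'   `control_arrays`.
#' @export
library_accounting <- function(n_singles = 0, n_pairs = 0, n_triples = 0,
                               n_quads = 0, n_control_arrays = 0) {
  fam <- 2L * (n_pairs + n_triples + n_quads)
  list(total = 2L * n_singles + fam + n_control_arrays,
       single_arrays = 2L * n_singles,
       paralog_family_arrays = fam,
       control_arrays = n_control_arrays)
}

#' Reagent count for one paralog-pair genetic-interaction test
#'
#' With two sibling arrays per target, testing one pair requires the two
#' pair arrays plus two single-gene arrays per member: six reagents,
#' versus at least thirty constructs per pair in earlier dual-guide
#' designs.
#'
#' @param arrays_per_target Sibling arrays per target (default 2).
#' @param n_members Genes in the family (default 2).
#' @return Number of reagents needed to score the family's interaction.
#' @export
reagents_per_family_test <- function(arrays_per_target = 2,
                                     n_members = 2) {
  arrays_per_target * (1L + n_members)
}
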