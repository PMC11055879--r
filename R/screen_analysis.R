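#' Combined knockout efficiency of a multi-gene perturbation
#'
#' Editing outcomes at independent loci multiply: with per-gene knockout
#' efficiency p, a complete n-gene knockout occurs in p^n of cells
#' (about 50 percent for a triple knockout at p = 0.8). Cells with
#' incomplete editing can mask severe higher-order phenotypes.
#'
#' @param per_gene_efficiency Probability a single gene is knocked out.
#' @param n_genes Number of genes perturbed together.
#' @return Fraction of cells with all `n_genes` knocked out.
#' @export
combined_knockout_efficiency <- function(per_gene_efficiency, n_genes) {
  stopifnot(per_gene_efficiency >= 0, per_gene_efficiency <= 1,
            n_genes >= 1)
  per_gene_efficiency^n_genes
}

family_key <- function(members) {
  vapply(members, function(m) paste(sort(m), collapse = ";"), "")
}

#' Aggregate clone-level fold changes to gene (or gene-set) level
#'
#' A target's fold change is the mean of all clone x replicate LFC
#' values of arrays annotated with that target; missing values are
#' skipped with the number used recorded.
#'
#' @param fc Fold-change data.frame with per-replicate `lfc.*` columns;
#'   `targets` holds the clone's target gene or family key.
#' @return data.frame `target`, `mean_fc`, `n_clones`, `n_values`.
#' @export
aggregate_gene_fc <- function(fc) {
  cols <- lfc_columns(fc)
  if (length(cols) == 0) stop("no replicate LFC columns", call. = FALSE)
  key <- family_key(split_targets(fc$targets))
  m <- as.matrix(fc[, cols, drop = FALSE])
  recs <- lapply(split(seq_len(nrow(fc)), key), function(idx) {
    vals <- as.vector(m[idx, , drop = FALSE])
    data.frame(target = key[idx][1],
               mean_fc = mean(vals, na.rm = TRUE),
               n_clones = length(idx),
               n_values = sum(!is.na(vals)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out[order(out$target), , drop = FALSE]
}

#' Call essential targets by fold-change threshold
#'
#' @param gene_fc [aggregate_gene_fc()] output.
#' @param threshold Essentiality threshold (default -1; strict `<`).
#' @return Character vector of essential targets.
#' @export
call_essential <- function(gene_fc, threshold = -1) {
  gene_fc$target[gene_fc$mean_fc < threshold]
}

#' Precision-recall curve against reference gene sets
#'
#' Targets are ranked by mean fold change ascending (most depleted
#' first); the walk is restricted to genes in the reference essential
#' (positives) or non-essential (negatives) sets, all others ignored.
#'
#' @param gene_fc [aggregate_gene_fc()] output.
#' @param essentials Reference essential gene set.
#' @param nonessentials Reference non-essential gene set.
#' @return data.frame `target`, `mean_fc`, `is_essential`, `recall`,
#'   `precision`, ordered by rank.
#' @export
precision_recall <- function(gene_fc, essentials, nonessentials) {
  sub <- gene_fc[gene_fc$target %in% c(essentials, nonessentials), ,
                 drop = FALSE]
  if (!any(sub$target %in% essentials) ||
      !any(sub$target %in% nonessentials))
    stop("reference sets have empty intersection with screened targets",
         call. = FALSE)
  sub <- sub[order(sub$mean_fc), , drop = FALSE]
  pos <- sub$target %in% essentials
  tp <- cumsum(pos)
  data.frame(target = sub$target, mean_fc = sub$mean_fc,
             is_essential = pos,
             recall = tp / sum(pos),
             precision = tp / seq_along(tp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify paralog-family genetic interactions at gene level
#'
#' Expected fold change is the sum of the members' single-target mean
#' fold changes; dLFC = observed - expected. Labels: `synthetic_lethal`
#' when dLFC < -1, `masking` when dLFC > +1 (strict), otherwise `none` —
#' except that a family whose expected fold change is more severe than
#' any fold change observed in the screen (`expected < screen_min_fc`)
#' is `untestable`, taking precedence over `masking` since buffering
#' cannot be distinguished from dynamic-range saturation there.
#' Families with missing member singles are reported as skipped.
#'
#' @param gene_fc [aggregate_gene_fc()] output covering both family
#'   targets and their member singles.
#' @param families List of character vectors (family members) or a
#'   character vector of semicolon-joined family keys.
#' @param screen_min_fc Most severe observed fold change in the screen;
#'   defaults to `min(gene_fc$mean_fc)` (clone-level aggregates).
#' @param sl_threshold,masking_threshold dLFC thresholds (defaults -1, +1).
#' @return data.frame `family`, `observed_fc`, `expected_fc`, `dlfc`,
#'   `label`, `skipped_reason`.
#' @export
classify_gi <- function(gene_fc, families, screen_min_fc = NULL,
                        sl_threshold = -1, masking_threshold = 1) {
  if (is.character(families))
    families <- strsplit(families, ";", fixed = TRUE)
  if (is.null(screen_min_fc)) screen_min_fc <- min(gene_fc$mean_fc)
  lut <- setNames(gene_fc$mean_fc, gene_fc$target)
  recs <- lapply(families, function(members) {
    members <- sort(members)
    key <- paste(members, collapse = ";")
    miss <- members[!(members %in% names(lut))]
    if (length(miss) > 0)
      return(data.frame(family = key, observed_fc = NA_real_,
                        expected_fc = NA_real_, dlfc = NA_real_,
                        label = NA_character_,
                        skipped_reason = paste0("missing_singles:",
                                                paste(miss, collapse = ",")),
                        stringsAsFactors = FALSE))
    if (!(key %in% names(lut)))
      return(data.frame(family = key, observed_fc = NA_real_,
                        expected_fc = NA_real_, dlfc = NA_real_,
                        label = NA_character_,
                        skipped_reason = "family_target_not_screened",
                        stringsAsFactors = FALSE))
    obs <- unname(lut[key])
    expd <- sum(lut[members])
    dlfc <- obs - expd
    label <- if (expd < screen_min_fc) "untestable"
             else if (dlfc < sl_threshold) "synthetic_lethal"
             else if (dlfc > masking_threshold) "masking"
             else "none"
    data.frame(family = key, observed_fc = obs, expected_fc = expd,
               dlfc = dlfc, label = label,
               skipped_reason = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Higher-order (trigenic/quadgenic) interaction calls with pair context
#'
#' Families of three or four members are classified under the same
#' additive null as pairs, and each constituent pair observed in the
#' screen is reported alongside so a higher-order call can be audited
#' against its composite pairs. A family is flagged
#' `explainable_by_pair` when the strongest constituent-pair dLFC is at
#' most `margin` above the family's own dLFC.
#'
#' @param gene_fc [aggregate_gene_fc()] output.
#' @param families List of 3-4 member families (or semicolon-joined keys).
#' @param screen_min_fc See [classify_gi()].
#' @param margin Attribution margin (default 0.5 LFC units).
#' @param ... Passed to [classify_gi()].
#' @return [classify_gi()] output plus `min_pair_dlfc`,
#'   `n_pairs_observed`, `explainable_by_pair` and a `pair_context`
#'   list-column of per-pair dLFC tables.
#' @export
higher_order_gi <- function(gene_fc, families, screen_min_fc = NULL,
                            margin = 0.5, ...) {
  if (is.character(families))
    families <- strsplit(families, ";", fixed = TRUE)
  base <- classify_gi(gene_fc, families, screen_min_fc, ...)
  ctx <- lapply(families, function(members) {
    members <- sort(members)
    if (length(members) < 3) return(NULL)
    prs <- utils::combn(members, 2, simplify = FALSE)
    keys <- family_key(prs)
    present <- keys %in% gene_fc$target
    if (!any(present)) return(NULL)
    classify_gi(gene_fc, prs[present], screen_min_fc, ...)
  })
  base$min_pair_dlfc <- vapply(ctx, function(p)
    if (is.null(p) || all(is.na(p$dlfc))) NA_real_
    else min(p$dlfc, na.rm = TRUE), numeric(1))
  base$n_pairs_observed <- vapply(ctx, function(p)
    if (is.null(p)) 0L else sum(!is.na(p$dlfc)), integer(1))
  base$explainable_by_pair <- !is.na(base$min_pair_dlfc) &
    !is.na(base$dlfc) & base$min_pair_dlfc <= base$dlfc + margin
  base$pair_context <- I(ctx)
  base
}
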