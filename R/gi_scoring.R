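#' Hit-calling thresholds for genetic-interaction scoring
#'
#' A pair is a synthetic-lethal hit when its dLFC falls below
#' `dlfc_threshold` and its Cohen's D exceeds `d_threshold` (both strict
#' inequalities; boundary values are misses).
#'
#' `pooled_sd_convention` selects the pooled standard deviation used in
#' Cohen's D: `as_printed` divides the radical by 2,
#' S = sqrt(sd_e^2 + sd_o^2) / 2, reproducing the formula as typeset;
#' `classical` is the usual pooled form S = sqrt((sd_e^2 + sd_o^2) / 2).
#' The two differ by exactly sqrt(2).
#'
#' @param dlfc_threshold dLFC hit threshold (default -1).
#' @param d_threshold Cohen's D hit threshold (default 0.8).
#' @param pooled_sd_convention `as_printed` (default) or `classical`.
#' @return A `gi_thresholds` list.
#' @export
gi_thresholds <- function(dlfc_threshold = -1, d_threshold = 0.8,
                          pooled_sd_convention = c("as_printed",
                                                   "classical")) {
  structure(list(dlfc_threshold = dlfc_threshold,
                 d_threshold = d_threshold,
                 pooled_sd_convention = match.arg(pooled_sd_convention)),
            class = "gi_thresholds")
}

targets_set_equal <- function(targets, want) {
  vapply(split_targets(targets), setequal, logical(1), y = want)
}

single_construct_rows <- function(fc, gene, control_labels) {
  singles <- fc$class %in% c("single_with_control_first",
                             "single_with_control_second")
  has_gene <- vapply(split_targets(fc$targets), function(t) {
    gene %in% t && all(setdiff(t, gene) %in% control_labels)
  }, logical(1))
  which(singles & has_gene)
}

#' Single mutant fitness of a gene
#'
#' SMF is the mean (and sample standard deviation) of the mean LFCs of
#' all constructs pairing the gene with a control guide, pooling both
#' orientations (gene_N and N_gene).
#'
#' @param fc Fold-change data.frame with `mean_lfc` populated.
#' @param gene Gene symbol.
#' @param control_labels Labels regarded as control targets.
#' @return List with `gene`, `smf_mean`, `smf_std` (NA when only one
#'   construct), `n_constructs`.
#' @export
compute_smf <- function(fc, gene, control_labels = c("control", "NT")) {
  rows <- single_construct_rows(fc, gene, control_labels)
  if (length(rows) == 0)
    stop("no gene-control construct for gene ", gene,
         "; pair unassayable", call. = FALSE)
  x <- fc$mean_lfc[rows]
  list(gene = gene, smf_mean = mean(x),
       smf_std = if (length(x) >= 2) sd(x) else NA_real_,
       n_constructs = length(x))
}

#' Expected double-mutant fitness under the additive (multiplicative) null
#'
#' expected mean = mu1 + mu2; expected sd = sqrt(sd1^2 + sd2^2).
#'
#' @param g1,g2 Results of [compute_smf()].
#' @return `c(mean = ..., std = ...)`.
#' @export
expected_dmf <- function(g1, g2) {
  c(mean = g1$smf_mean + g2$smf_mean,
    std = sqrt(g1$smf_std^2 + g2$smf_std^2))
}

#' Modified Cohen's D between expected and observed LFC distributions
#'
#' D = (expected mean - observed mean) / S_pooled, so an observed
#' distribution more negative than expected (the synthetic-lethal
#' direction) gives D > 0. See [gi_thresholds()] for the two pooled-SD
#' conventions.
#'
#' @param expected,observed Length-2 vectors `c(mean, std)` (named or
#'   positional).
#' @param convention `as_printed` or `classical`.
#' @return Cohen's D (scalar).
#' @export
cohens_d <- function(expected, observed,
                     convention = c("as_printed", "classical")) {
  convention <- match.arg(convention)
  e_m <- expected[[1]]; e_s <- expected[[2]]
  o_m <- observed[[1]]; o_s <- observed[[2]]
  s_pooled <- switch(convention,
                     as_printed = sqrt(e_s^2 + o_s^2) / 2,
                     classical = sqrt((e_s^2 + o_s^2) / 2))
  if (!is.finite(s_pooled) || s_pooled == 0)
    stop("pooled standard deviation is zero or undefined; ",
         "effect size undefined", call. = FALSE)
  (e_m - o_m) / s_pooled
}

#' Score a paralog pair's genetic interaction
#'
#' Computes SMFs, the expected double-mutant distribution, the observed
#' distribution over all pair constructs, dLFC (observed - expected
#' mean), Cohen's D, and the hit call. Gene labels are sorted so the
#' record is symmetric in its arguments.
#'
#' @param fc Fold-change data.frame with `mean_lfc`.
#' @param gene1,gene2 Gene symbols.
#' @param thresholds A [gi_thresholds()].
#' @param control_labels Labels regarded as control targets.
#' @return One-row data.frame with columns `gene1`, `gene2`, `smf1`,
#'   `smf2`, `observed_lfc`, `observed_std`, `expected_lfc`,
#'   `expected_std`, `dlfc`, `cohens_d`, `n_constructs`, `hit`.
#' @export
score_pair <- function(fc, gene1, gene2, thresholds = gi_thresholds(),
                       control_labels = c("control", "NT")) {
  genes <- sort(c(gene1, gene2))
  g1 <- compute_smf(fc, genes[1], control_labels)
  g2 <- compute_smf(fc, genes[2], control_labels)
  rows <- which(fc$class == "pair" & targets_set_equal(fc$targets, genes))
  if (length(rows) == 0)
    stop("no pair construct targeting ", genes[1], " and ", genes[2],
         call. = FALSE)
  obs <- fc$mean_lfc[rows]
  expd <- expected_dmf(g1, g2)
  obs_mean <- mean(obs)
  obs_std <- if (length(obs) >= 2) sd(obs) else NA_real_
  d <- cohens_d(expd, c(obs_mean, obs_std),
                thresholds$pooled_sd_convention)
  dlfc <- obs_mean - expd[["mean"]]
  data.frame(gene1 = genes[1], gene2 = genes[2],
             smf1 = g1$smf_mean, smf2 = g2$smf_mean,
             observed_lfc = obs_mean, observed_std = obs_std,
             expected_lfc = expd[["mean"]], expected_std = expd[["std"]],
             dlfc = dlfc, cohens_d = d, n_constructs = length(rows),
             hit = (dlfc < thresholds$dlfc_threshold) &&
                   (d > thresholds$d_threshold),
             stringsAsFactors = FALSE)
}

#' Score every assayed pair in a screen
#'
#' Pairs are taken from the distinct target sets of `pair`-class
#' constructs. Pairs whose SMFs or effect size cannot be computed are
#' reported with status `unassayed` (not as misses).
#'
#' @param fc Fold-change data.frame with `mean_lfc`.
#' @param thresholds A [gi_thresholds()].
#' @param control_labels Labels regarded as control targets.
#' @return data.frame, one row per pair, with the [score_pair()] columns
#'   plus `status` in `hit`/`miss`/`unassayed`.
#' @export
score_all_pairs <- function(fc, thresholds = gi_thresholds(),
                            control_labels = c("control", "NT")) {
  pair_targets <- unique(vapply(
    split_targets(fc$targets[fc$class == "pair"]),
    function(t) paste(sort(t), collapse = ";"), ""))
  recs <- lapply(pair_targets, function(key) {
    genes <- strsplit(key, ";", fixed = TRUE)[[1]]
    rec <- tryCatch(score_pair(fc, genes[1], genes[2], thresholds,
                               control_labels),
                    error = function(e) NULL)
    if (is.null(rec)) {
      data.frame(gene1 = genes[1], gene2 = genes[2], smf1 = NA_real_,
                 smf2 = NA_real_, observed_lfc = NA_real_,
                 observed_std = NA_real_, expected_lfc = NA_real_,
                 expected_std = NA_real_, dlfc = NA_real_,
                 cohens_d = NA_real_, n_constructs = NA_integer_,
                 hit = NA, status = "unassayed",
                 stringsAsFactors = FALSE)
    } else {
      rec$status <- if (isTRUE(rec$hit)) "hit" else "miss"
      rec
    }
  })
  do.call(rbind, recs)
}
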