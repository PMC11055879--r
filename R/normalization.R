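#' Normalization configuration
#'
#' Parameters of the count-to-LFC pipeline: pseudocount added to every
#' construct, target mean reads per construct after depth scaling, and
#' the grouping scheme used for mode-centering.
#'
#' Grouping schemes mirror the conventions of the published paralog
#' screens: `three_group` centers gene_N, N_gene and pair constructs
#' independently; `control_mode_only` subtracts the mode of designated
#' control constructs from all constructs (with optional removal of
#' whole gene families beforehand); `single_orientation` is the same
#' control-mode subtraction for libraries with a single singleton
#' orientation.
#'
#' @param pseudocount Reads added to every count (default 5).
#' @param target_mean_reads Post-normalization mean reads per construct
#'   (default 500).
#' @param grouping_scheme One of `three_group`, `control_mode_only`,
#'   `single_orientation`.
#' @param control_labels Target labels regarded as controls
#'   (non-essential / non-targeting guides).
#' @param excluded_families Gene symbols whose constructs are dropped
#'   before any computation (e.g. a family known to cross-react).
#' @return A `normalization_config` list.
#' @export
normalization_config <- function(pseudocount = 5,
                                 target_mean_reads = 500,
                                 grouping_scheme = c("three_group",
                                                     "control_mode_only",
                                                     "single_orientation"),
                                 control_labels = c("control", "NT"),
                                 excluded_families = character()) {
  grouping_scheme <- match.arg(grouping_scheme)
  stopifnot(pseudocount >= 0, target_mean_reads > 0)
  structure(list(pseudocount = pseudocount,
                 target_mean_reads = target_mean_reads,
                 grouping_scheme = grouping_scheme,
                 control_labels = control_labels,
                 excluded_families = excluded_families),
            class = "normalization_config")
}

#' Read a per-study normalization config from YAML
#'
#' YAML keys map directly onto [normalization_config()] arguments.
#'
#' @param path YAML path.
#' @return A `normalization_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(normalization_config, y)
}

#' Depth-normalize a count matrix
#'
#' Per sample: the pseudocount is added to every construct, then counts
#' are scaled so the mean normalized reads per construct equals
#' `target_mean_reads` (equivalently a total of `target_mean_reads * K`
#' for K constructs).
#'
#' @param cm A [count_matrix()].
#' @param cfg A [normalization_config()].
#' @return A `count_matrix` whose `counts` are real-valued normalized reads.
#' @export
normalize_depth <- function(cm, cfg = normalization_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  x <- cm$counts + cfg$pseudocount
  mu <- colMeans(x)
  if (any(mu == 0))
    stop("degenerate sample(s) with all-zero counts and pseudocount 0: ",
         paste(colnames(x)[mu == 0], collapse = ", "), call. = FALSE)
  x <- sweep(x, 2, cfg$target_mean_reads / mu, `*`)
  cm$counts <- x
  cm
}

#' Compute per-replicate log2 fold changes versus the reference
#'
#' LFC(construct, endpoint sample) = log2(normalized endpoint reads /
#' normalized reference reads). Multiple reference samples (e.g. two T0
#' replicates) are averaged before division.
#'
#' @param cm A depth-normalized `count_matrix`.
#' @return A fold-change data.frame with columns `construct_id`,
#'   `targets`, `class`, `study_id`, `cell_line` and one `lfc.<sample>`
#'   column per endpoint sample.
#' @export
compute_lfc <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  ref_ids <- cm$samples$sample_id[cm$samples$role == "reference"]
  if (length(ref_ids) == 0)
    stop("no reference sample designated", call. = FALSE)
  end_ids <- cm$samples$sample_id[cm$samples$role == "endpoint"]
  ref <- rowMeans(cm$counts[, ref_ids, drop = FALSE])
  lfc <- log2(sweep(cm$counts[, end_ids, drop = FALSE], 1, ref, `/`))
  colnames(lfc) <- paste0("lfc.", end_ids)
  out <- data.frame(construct_id = cm$manifest$construct_id,
                    targets = cm$manifest$targets,
                    class = cm$manifest$class,
                    study_id = cm$manifest$study_id,
                    cell_line = cm$manifest$cell_line,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(lfc))
}

#' Estimate the mode of a sample
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth
#' evaluated on a 512-point grid spanning the sample's range; the mode is
#' the grid argmax, with ties broken toward the value closest to 0.
#' Degenerate samples (length 1 or zero spread) return their single value.
#'
#' @param x Numeric vector.
#' @return The estimated mode (scalar).
#' @export
estimate_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("cannot estimate the mode of an empty sample",
                           call. = FALSE)
  if (length(x) == 1 || diff(range(x)) == 0) return(x[1])
  d <- density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  peak <- d$x[d$y >= max(d$y) - 1e-12]
  peak[which.min(abs(peak))]
}

centering_groups <- function(fc, cfg) {
  is_control <- fc$class == "control" |
    vapply(split_targets(fc$targets),
           function(t) all(t %in% cfg$control_labels), logical(1))
  switch(cfg$grouping_scheme,
         three_group = {
           g <- ifelse(fc$class == "single_with_control_second", "gene_N",
                ifelse(fc$class == "single_with_control_first", "N_gene",
                       "A_B"))
           split(seq_len(nrow(fc)), g)
         },
         # control-mode schemes: one offset from control constructs,
         # applied to everything
         {
           if (!any(is_control))
             stop("no control constructs found for control-mode centering",
                  call. = FALSE)
           list(all = seq_len(nrow(fc)))
         })
}

#' Mode-center fold changes by construct group
#'
#' Each group's LFCs are shifted so the group's estimated mode is zero;
#' the shift is additive (subtracting the mode), applied per replicate
#' column, and the offsets are recorded in the `centering_offsets`
#' attribute. Under `three_group` the gene_N, N_gene and remaining
#' constructs are centered independently then merged; under the
#' control-mode schemes a single offset — the mode of control constructs —
#' is subtracted from every construct. Constructs targeting
#' `excluded_families` are dropped before any computation.
#'
#' @param fc Fold-change data.frame from [compute_lfc()].
#' @param cfg A [normalization_config()].
#' @return The centered fold-change data.frame.
#' @export
center_groups <- function(fc, cfg = normalization_config()) {
  if (length(cfg$excluded_families) > 0) {
    hit_fam <- vapply(split_targets(fc$targets),
                      function(t) any(t %in% cfg$excluded_families),
                      logical(1))
    fc <- fc[!hit_fam, , drop = FALSE]
  }
  cols <- lfc_columns(fc)
  if (length(cols) == 0) stop("no lfc columns to center", call. = FALSE)
  groups <- centering_groups(fc, cfg)
  if (any(lengths(groups) == 0)) stop("empty centering group", call. = FALSE)
  offsets <- matrix(NA_real_, length(groups), length(cols),
                    dimnames = list(names(groups), cols))
  for (j in cols) {
    for (g in names(groups)) {
      idx <- groups[[g]]
      src <- idx
      if (cfg$grouping_scheme != "three_group") {
        is_control <- fc$class == "control" |
          vapply(split_targets(fc$targets),
                 function(t) all(t %in% cfg$control_labels), logical(1))
        src <- which(is_control)
      }
      off <- estimate_mode(fc[[j]][src])
      fc[[j]][idx] <- fc[[j]][idx] - off
      offsets[g, j] <- off
    }
  }
  attr(fc, "centering_offsets") <- offsets
  fc
}

#' Average replicate fold changes
#'
#' Populates `mean_lfc` as the arithmetic mean of the per-replicate LFC
#' columns; missing replicate values are skipped, with the number of
#' values used recorded in `n_replicates_used`.
#'
#' @param fc Fold-change data.frame.
#' @return The data.frame with `mean_lfc` and `n_replicates_used` added.
#' @export
mean_over_replicates <- function(fc) {
  cols <- lfc_columns(fc)
  if (length(cols) == 0) stop("no replicate LFC columns", call. = FALSE)
  m <- as.matrix(fc[, cols, drop = FALSE])
  fc$mean_lfc <- rowMeans(m, na.rm = TRUE)
  fc$n_replicates_used <- rowSums(!is.na(m))
  fc
}

#' Full counts-to-fold-change pipeline
#'
#' Pseudocount, depth normalization, per-replicate LFC versus the
#' reference, group mode-centering, then replicate averaging — in that
#' order.
#'
#' @param cm A [count_matrix()].
#' @param cfg A [normalization_config()].
#' @return A centered, replicate-averaged fold-change data.frame.
#' @export
normalize_counts <- function(cm, cfg = normalization_config()) {
  fc <- compute_lfc(normalize_depth(cm, cfg))
  fc <- center_groups(fc, cfg)
  mean_over_replicates(fc)
}
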