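mask_to_matrix <- function(masks) {
  n <- nchar(masks[1])
  m <- do.call(rbind, lapply(strsplit(masks, ""),
                             function(b) as.integer(b)))
  colnames(m) <- paste0("pos", seq_len(n))
  m
}

mask_popcount <- function(masks) {
  vapply(strsplit(masks, ""), function(b) sum(b == "1"), integer(1))
}

#' Enumerate a full essential/non-essential titration design
#'
#' One array per (pool, mask) combination, where the mask is the binary
#' pattern of essential (1) versus non-essential (0) guides across array
#' positions: `n_pools * 2^n_positions` arrays in total (3 x 2^7 = 384
#' for the 7-position, 3-pool design).
#'
#' @param n_positions Guide positions per array (default 7).
#' @param n_pools Independent pools with distinct guide sets (default 3).
#' @param orientation `forward` or `reverse` (metadata; the reverse
#'   design carries the same guides with position i mapped to
#'   n_positions + 1 - i).
#' @return data.frame with `array_id`, `pool`, `mask` (0/1 string),
#'   `n_essential`, `orientation`.
#' @export
enumerate_design <- function(n_positions = 7, n_pools = 3,
                             orientation = "forward") {
  stopifnot(n_positions >= 1, n_pools >= 1)
  masks <- vapply(0:(2^n_positions - 1), function(i)
    paste(rev(as.integer(intToBits(i))[seq_len(n_positions)]),
          collapse = ""), "")
  design <- expand.grid(mask = masks, pool = seq_len(n_pools),
                        stringsAsFactors = FALSE)
  design <- design[order(design$pool, design$mask), c("pool", "mask")]
  design$array_id <- sprintf("pool%d_%s", design$pool, design$mask)
  design$n_essential <- mask_popcount(design$mask)
  design$orientation <- orientation
  rownames(design) <- NULL
  design[, c("array_id", "pool", "mask", "n_essential", "orientation")]
}

design_lfc_cols <- function(design) {
  cols <- grep("^lfc", names(design), value = TRUE)
  if (length(cols) == 0)
    stop("design carries no lfc column", call. = FALSE)
  cols
}

#' Normalize array fold changes to the all-non-essential controls
#'
#' Per LFC column (sample/timepoint), every array's fold change is
#' shifted so the mean of arrays with no essential guide (all-zero mask)
#' is exactly zero. Differences between any two arrays are unchanged.
#'
#' @param design An [enumerate_design()] data.frame with one or more
#'   `lfc*` columns.
#' @return The design with shifted LFCs and a `nonessential_offsets`
#'   attribute recording the per-column shift.
#' @export
normalize_to_all_nonessential <- function(design) {
  cols <- design_lfc_cols(design)
  ctrl <- design$n_essential == 0
  if (!any(ctrl))
    stop("no all-non-essential array to normalize against", call. = FALSE)
  offs <- vapply(cols, function(j) mean(design[[j]][ctrl]), numeric(1))
  for (j in cols) design[[j]] <- design[[j]] - offs[[j]]
  attr(design, "nonessential_offsets") <- offs
  design
}

#' Retain arrays encoding few essential guides
#'
#' Keeps arrays whose mask popcount is at most `max_essentials`; with the
#' default 2 on the full 3-pool, 7-position design this retains
#' 3 * (1 + 7 + 21) = 87 arrays.
#'
#' @param design Design data.frame.
#' @param max_essentials Maximum essential guides per retained array.
#' @return Filtered design.
#' @export
filter_low_order <- function(design, max_essentials = 2) {
  design[design$n_essential <= max_essentials, , drop = FALSE]
}

#' Fit the additive (multiplicative-null) position model
#'
#' Ordinary least squares of normalized fold change on the binary
#' position-encoding matrix A (A[i, j] = 1 iff array i carries an
#' essential guide at position j), with an intercept reported separately;
#' after all-non-essential normalization the intercept should be near
#' zero. The beta coefficients estimate the single-knockout phenotype at
#' each position.
#'
#' @param design Design data.frame with an LFC column.
#' @param lfc_col Which LFC column to fit (default the first `lfc*`).
#' @param per_pool Also fit each pool separately.
#' @return An `array_model_fit` list: `beta` (named per position),
#'   `intercept`, `k_rows`, `lfc_col`, and optionally `per_pool_beta`.
#' @export
fit_additive_model <- function(design, lfc_col = NULL, per_pool = FALSE) {
  if (is.null(lfc_col)) lfc_col <- design_lfc_cols(design)[1]
  A <- mask_to_matrix(design$mask)
  y <- design[[lfc_col]]
  X <- cbind(`(Intercept)` = 1, A)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; dependent columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fit <- lm(y ~ A)
  beta <- setNames(coef(fit)[-1], colnames(A))
  out <- list(beta = beta, intercept = unname(coef(fit)[1]),
              k_rows = nrow(design), lfc_col = lfc_col)
  if (per_pool) {
    out$per_pool_beta <- lapply(split(seq_len(nrow(design)), design$pool),
      function(idx) {
        f <- lm(design[[lfc_col]][idx] ~ mask_to_matrix(design$mask[idx]))
        setNames(coef(f)[-1], colnames(A))
      })
  }
  structure(out, class = "array_model_fit")
}

#' Predict array fitness from the additive fit and score per pool
#'
#' The prediction for an array is the intercept plus the sum of the
#' fitted beta coefficients of its essential positions. R-squared is
#' computed per pool between predicted and observed fold change over
#' arrays with at most `order` essential guides (matching the
#' low-order filtered fit).
#'
#' @param fit An [fit_additive_model()] result.
#' @param design Design data.frame with the fitted LFC column.
#' @param order Maximum essential guides per scored array (default 2).
#' @return List with `predictions` (the scored subset of the design plus
#'   a `predicted` column) and `r_squared` (named per pool).
#' @export
predict_and_score <- function(fit, design, order = 2) {
  stopifnot(inherits(fit, "array_model_fit"))
  sub <- filter_low_order(design, order)
  A <- mask_to_matrix(sub$mask)
  sub$predicted <- fit$intercept + as.vector(A %*% fit$beta)
  y <- sub[[fit$lfc_col]]
  r2 <- vapply(split(seq_len(nrow(sub)), sub$pool), function(idx) {
    1 - sum((y[idx] - sub$predicted[idx])^2) /
      sum((y[idx] - mean(y[idx]))^2)
  }, numeric(1))
  list(predictions = sub, r_squared = r2)
}

#' Mean fold change of single-essential arrays by position
#'
#' @param design Design data.frame with an LFC column.
#' @param lfc_col LFC column (default the first `lfc*`).
#' @return data.frame `position`, `mean_lfc`, `n_arrays`; positions with
#'   no single-essential array are absent.
#' @export
position_effects <- function(design, lfc_col = NULL) {
  if (is.null(lfc_col)) lfc_col <- design_lfc_cols(design)[1]
  sub <- design[design$n_essential == 1, , drop = FALSE]
  pos <- vapply(strsplit(sub$mask, ""), function(b) which(b == "1"),
                integer(1))
  agg <- tapply(sub[[lfc_col]], pos, mean)
  data.frame(position = as.integer(names(agg)),
             mean_lfc = as.vector(agg),
             n_arrays = as.vector(table(pos)),
             row.names = NULL)
}

#' Forward/reverse comparison of single-essential arrays
#'
#' In the reverse design the guide at forward position i sits at array
#' position n + 1 - i. For each (pool, guide), the fold change of the
#' forward single-essential array is paired with that of the reverse
#' array carrying the same guide; deviation = forward - reverse.
#' Position-independent guide effects fall on the diagonal; positions
#' with attenuated editing deviate from it.
#'
#' @param design_fwd,design_rev Forward and reverse designs with an LFC
#'   column each.
#' @param lfc_col LFC column name shared by both designs.
#' @return data.frame `pool`, `guide` (forward position index),
#'   `forward_lfc`, `reverse_lfc`, `deviation`.
#' @export
forward_vs_reverse <- function(design_fwd, design_rev, lfc_col = NULL) {
  if (is.null(lfc_col)) lfc_col <- design_lfc_cols(design_fwd)[1]
  n <- nchar(design_fwd$mask[1])
  grab <- function(design, map_pos) {
    sub <- design[design$n_essential == 1, , drop = FALSE]
    pos <- vapply(strsplit(sub$mask, ""), function(b) which(b == "1"),
                  integer(1))
    data.frame(pool = sub$pool, guide = map_pos(pos),
               lfc = sub[[lfc_col]], stringsAsFactors = FALSE)
  }
  fwd <- grab(design_fwd, identity)
  rev_ <- grab(design_rev, function(p) n + 1L - p)
  merged <- merge(fwd, rev_, by = c("pool", "guide"),
                  suffixes = c("_forward", "_reverse"))
  data.frame(pool = merged$pool, guide = merged$guide,
             forward_lfc = merged$lfc_forward,
             reverse_lfc = merged$lfc_reverse,
             deviation = merged$lfc_forward - merged$lfc_reverse)
}
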