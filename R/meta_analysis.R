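#' Canonical unordered pair key
#'
#' @param g1,g2 Gene symbol vectors.
#' @return Character vector `min|max`, symmetric in its arguments.
#' @export
pair_key <- function(g1, g2) {
  paste(pmin(g1, g2), pmax(g1, g2), sep = "|")
}

#' Build a tri-state hit matrix across screens
#'
#' Assembles per-screen genetic-interaction tables into a pairs x screens
#' matrix with states `hit`, `miss` and `unassayed`. A pair unassayed in
#' a screen contributes to neither hit nor miss sums downstream.
#'
#' @param screens Named list of per-screen GI data.frames (the
#'   [score_all_pairs()] format with `gene1`, `gene2`, `status`); names
#'   are screen ids.
#' @param screen_info data.frame with columns `screen_id`, `study_id`
#'   (and optionally `cell_line`) mapping screens to studies.
#' @return A `hit_matrix` list with `state` (character matrix), `pairs`,
#'   and `screen_info`.
#' @export
hit_matrix <- function(screens, screen_info) {
  stopifnot(is.list(screens), !is.null(names(screens)),
            all(c("screen_id", "study_id") %in% names(screen_info)))
  if (!setequal(names(screens), screen_info$screen_id))
    stop("screen ids do not match screen_info", call. = FALSE)
  keys <- lapply(screens, function(g) pair_key(g$gene1, g$gene2))
  pairs <- sort(unique(unlist(keys)))
  state <- matrix("unassayed", length(pairs), length(screens),
                  dimnames = list(pairs, names(screens)))
  for (s in names(screens)) {
    g <- screens[[s]]
    state[pair_key(g$gene1, g$gene2), s] <- g$status
  }
  structure(list(pairs = pairs, state = state,
                 screen_info = screen_info[
                   match(names(screens), screen_info$screen_id), ,
                   drop = FALSE]),
            class = "hit_matrix")
}

screen_hit_set <- function(hm, screen_id) {
  hm$pairs[hm$state[, screen_id] == "hit"]
}

#' Jaccard similarity of two hit sets
#'
#' |A intersect B| / |A union B|; defined as 0 when both sets are empty
#' (two screens with no hits carry no replicability evidence).
#'
#' @param hits_a,hits_b Character vectors of pair keys (or any labels).
#' @return Jaccard coefficient in [0, 1].
#' @export
jaccard <- function(hits_a, hits_b) {
  u <- union(hits_a, hits_b)
  if (length(u) == 0) return(0)
  length(intersect(hits_a, hits_b)) / length(u)
}

#' Per-study platform weights from within-study replicability
#'
#' For each study, the Jaccard coefficient of the hit sets of every
#' unordered pair of its screens (cell lines) is computed; the platform
#' weight is the median of those coefficients (for an even count, the
#' mean of the two central order statistics). Studies with a single
#' screen have no within-study pair and are excluded with a warning.
#'
#' @param hm A [hit_matrix()].
#' @return data.frame with `study_id`, `weight`, `n_pairs_of_screens`,
#'   and a `pairwise_jaccards` list-column.
#' @export
platform_weights <- function(hm) {
  studies <- unique(hm$screen_info$study_id)
  recs <- lapply(studies, function(st) {
    sc <- hm$screen_info$screen_id[hm$screen_info$study_id == st]
    if (length(sc) < 2) {
      warning("study ", st, " has a single screen; weight undefined, ",
              "study excluded", call. = FALSE)
      return(NULL)
    }
    cmb <- utils::combn(sc, 2)
    jj <- apply(cmb, 2, function(p)
      jaccard(screen_hit_set(hm, p[1]), screen_hit_set(hm, p[2])))
    data.frame(study_id = st, weight = median(jj),
               n_pairs_of_screens = length(jj),
               pairwise_jaccards = I(list(jj)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Weighted paralog confidence scores and gold-standard candidates
#'
#' A pair's paralog score is the sum of the platform weights of screens
#' in which it is a hit minus the sum of weights of screens in which it
#' was assayed but missed; unassayed screens contribute nothing. A pair
#' is a gold-standard candidate when its score strictly exceeds
#' `score_threshold` and it is a hit in at least two distinct studies.
#'
#' @param hm A [hit_matrix()].
#' @param weights Output of [platform_weights()].
#' @param score_threshold Gold-standard score threshold (default 0.25).
#' @return data.frame with `pair`, `score`, `n_studies_hit`,
#'   `n_screens_assayed`, `gold_standard`.
#' @export
paralog_scores <- function(hm, weights, score_threshold = 0.25) {
  w <- setNames(weights$weight, weights$study_id)
  keep <- hm$screen_info$study_id %in% names(w)
  info <- hm$screen_info[keep, , drop = FALSE]
  st <- hm$state[, info$screen_id, drop = FALSE]
  sw <- w[info$study_id]
  score <- as.vector((st == "hit") %*% sw - (st == "miss") %*% sw)
  n_studies_hit <- apply(st == "hit", 1, function(h)
    length(unique(info$study_id[h])))
  data.frame(pair = hm$pairs, score = score,
             n_studies_hit = n_studies_hit,
             n_screens_assayed = rowSums(st != "unassayed"),
             gold_standard = score > score_threshold & n_studies_hit >= 2,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Recall of a screen against a gold-standard set
#'
#' |hits intersect gold| / |assayed intersect gold|. Returns NA when the
#' screen assays no gold pair.
#'
#' @param screen_hits Pairs called hits by the screen.
#' @param screen_assayed Pairs assayed by the screen (hits plus misses).
#' @param gold Gold-standard pair set (must be nonempty).
#' @return Recall in [0, 1], or NA.
#' @export
recall_vs_gold <- function(screen_hits, screen_assayed, gold) {
  if (length(gold) == 0) stop("gold set is empty", call. = FALSE)
  denom <- length(intersect(screen_assayed, gold))
  if (denom == 0) return(NA_real_)
  length(intersect(screen_hits, gold)) / denom
}
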