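#' Configuration for a simulated multiplex paralog screen
#'
#' The generator emulates the statistical structure of the published
#' dual-guide paralog screens: per-gene single-mutant fitness drawn from
#' an essential or a neutral distribution, planted pairwise (and
#' optionally trigenic) interactions, gene-control constructs in both
#' orientations, dual-target constructs combining the genes' guides,
#' negative-control constructs, replicate count noise, and a per-study
#' fidelity multiplier on construct noise.
#'
#' Construct arithmetic: each gene gets `constructs_per_target`
#' gene-control constructs in each orientation (gene_N and N_gene), and
#' each assayed pair `2 * constructs_per_target^2` dual-target
#' constructs (all guide combinations in both orientations), mirroring
#' the combinatorial construction of dual-guide libraries, which used at
#' least thirty constructs per pair.
#'
#' @param n_genes Number of genes.
#' @param fraction_essential Fraction of genes drawn from the essential
#'   fitness distribution.
#' @param smf_essential,smf_neutral Length-2 vectors `c(mean, sd)` of
#'   the single-mutant-fitness distributions (log2 units).
#' @param sl_pairs data.frame `gene1`, `gene2`, `dlfc` of planted
#'   interactions (NULL for none).
#' @param trigenic_effects data.frame `gene1`, `gene2`, `gene3`,
#'   `effect` of planted trigenic interactions (NULL for none).
#' @param n_null_pairs Additional assayed pairs with no planted
#'   interaction.
#' @param constructs_per_target Guides per gene (see construct
#'   arithmetic above).
#' @param replicates Endpoint replicates.
#' @param reference_depth Mean reference (plasmid) reads per construct.
#' @param noise_sd Construct-level LFC noise sd (one draw per construct,
#'   shared across replicates).
#' @param dispersion Negative-binomial overdispersion of endpoint counts
#'   (`size = 1/dispersion`); 0 gives exact expected counts.
#' @param platform_fidelity Multiplier on `noise_sd` (>1 = noisier
#'   platform).
#' @param n_control_constructs Control (non-targeting pair) constructs.
#' @param control_label Label used for control guides.
#' @param seed Mandatory integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 30,
                              fraction_essential = 0.25,
                              smf_essential = c(mean = -2, sd = 0.5),
                              smf_neutral = c(mean = 0, sd = 0.1),
                              sl_pairs = NULL,
                              trigenic_effects = NULL,
                              n_null_pairs = 20,
                              constructs_per_target = 4,
                              replicates = 3,
                              reference_depth = 500,
                              noise_sd = 0.3,
                              dispersion = 0.01,
                              platform_fidelity = 1,
                              n_control_constructs = 20,
                              control_label = "NT",
                              seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(fraction_essential >= 0, fraction_essential <= 1,
            smf_essential[2] >= 0, smf_neutral[2] >= 0,
            noise_sd >= 0, dispersion >= 0, reference_depth > 0,
            constructs_per_target >= 1, replicates >= 1)
  structure(list(n_genes = n_genes,
                 fraction_essential = fraction_essential,
                 smf_essential = smf_essential,
                 smf_neutral = smf_neutral,
                 sl_pairs = sl_pairs,
                 trigenic_effects = trigenic_effects,
                 n_null_pairs = n_null_pairs,
                 constructs_per_target = constructs_per_target,
                 replicates = replicates,
                 reference_depth = reference_depth,
                 noise_sd = noise_sd,
                 dispersion = dispersion,
                 platform_fidelity = platform_fidelity,
                 n_control_constructs = n_control_constructs,
                 control_label = control_label,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

sim_gene_names <- function(n) sprintf("G%03d", seq_len(n))

#' Simulate a multiplex paralog screen
#'
#' Constructs' true LFCs are the sum of their targets' single-mutant
#' fitnesses plus any planted interaction plus construct-level Gaussian
#' noise (`noise_sd * platform_fidelity`). Reference counts are
#' lognormal around `reference_depth`; endpoint counts are
#' negative-binomial around `reference * 2^trueLFC` with the stated
#' overdispersion. With `dispersion = 0` counts equal their expected
#' values exactly (possibly non-integer), so the noiseless round-trip
#' through normalization is exact.
#'
#' @param cfg A [screen_sim_config()].
#' @param study_id,cell_line Labels recorded in the manifest.
#' @return List with `counts` (a [count_matrix()]) and `truth`
#'   (`genes`, `pairs`, `triples`, `constructs` tables of all planted
#'   quantities).
#' @export
simulate_screen <- function(cfg, study_id = "sim_study",
                            cell_line = "sim_line") {
  stopifnot(inherits(cfg, "screen_sim_config"))
  set.seed(cfg$seed)
  genes <- sim_gene_names(cfg$n_genes)
  n_ess <- round(cfg$n_genes * cfg$fraction_essential)
  essential <- c(rep(TRUE, n_ess), rep(FALSE, cfg$n_genes - n_ess))
  smf <- ifelse(essential,
                rnorm(cfg$n_genes, cfg$smf_essential[1],
                      cfg$smf_essential[2]),
                rnorm(cfg$n_genes, cfg$smf_neutral[1],
                      cfg$smf_neutral[2]))
  names(smf) <- genes
  gene_truth <- data.frame(gene = genes, essential = essential,
                           smf = unname(smf), stringsAsFactors = FALSE)

  sl <- cfg$sl_pairs
  if (!is.null(sl)) {
    bad <- !(sl$gene1 %in% genes) | !(sl$gene2 %in% genes)
    if (any(bad))
      stop("sl_pairs reference genes outside the simulated set: ",
           paste(unique(c(sl$gene1[bad], sl$gene2[bad])), collapse = ", "),
           call. = FALSE)
  }
  planted_keys <- if (is.null(sl)) character() else
    pair_key(sl$gene1, sl$gene2)
  # null pairs among neutral genes: paralog pairs are depleted of
  # essentials, so the group's LFC mode is a well-defined zero peak
  neutral_genes <- genes[!essential]
  all_pairs <- utils::combn(neutral_genes, 2)
  all_keys <- pair_key(all_pairs[1, ], all_pairs[2, ])
  avail <- which(!(all_keys %in% planted_keys))
  n_null <- min(cfg$n_null_pairs, length(avail))
  null_idx <- if (n_null > 0) sample(avail, n_null) else integer()
  pairs <- rbind(
    if (!is.null(sl))
      data.frame(gene1 = pmin(sl$gene1, sl$gene2),
                 gene2 = pmax(sl$gene1, sl$gene2),
                 dlfc = sl$dlfc, stringsAsFactors = FALSE),
    if (n_null > 0)
      data.frame(gene1 = all_pairs[1, null_idx],
                 gene2 = all_pairs[2, null_idx],
                 dlfc = 0, stringsAsFactors = FALSE))
  if (is.null(pairs))
    pairs <- data.frame(gene1 = character(), gene2 = character(),
                        dlfc = numeric(), stringsAsFactors = FALSE)

  cpt <- cfg$constructs_per_target
  ctl <- cfg$control_label
  rows <- list()
  add <- function(id, targets, class, true_lfc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      construct_id = id, targets = targets, class = class,
      true_lfc = true_lfc, stringsAsFactors = FALSE)
  }
  for (g in genes) {
    for (k in seq_len(cpt)) {
      add(sprintf("%s_%s_g%d", g, ctl, k), paste(g, ctl, sep = ";"),
          "single_with_control_second", smf[g])
      add(sprintf("%s_%s_g%d", ctl, g, k), paste(ctl, g, sep = ";"),
          "single_with_control_first", smf[g])
    }
  }
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
      base <- smf[g1] + smf[g2] + pairs$dlfc[i]
      for (k in seq_len(2 * cpt^2))
        add(sprintf("%s_%s_p%d", g1, g2, k), paste(g1, g2, sep = ";"),
            "pair", base)
    }
  }
  tri <- cfg$trigenic_effects
  if (!is.null(tri)) {
    pair_dlfc <- setNames(pairs$dlfc, pair_key(pairs$gene1, pairs$gene2))
    for (i in seq_len(nrow(tri))) {
      gg <- sort(c(tri$gene1[i], tri$gene2[i], tri$gene3[i]))
      cps <- utils::combn(gg, 2)
      pw <- sum(pair_dlfc[pair_key(cps[1, ], cps[2, ])], na.rm = TRUE)
      base <- sum(smf[gg]) + pw + tri$effect[i]
      for (k in seq_len(2 * cpt))
        add(sprintf("%s_t%d", paste(gg, collapse = "_"), k),
            paste(gg, collapse = ";"), "triple", base)
    }
  }
  for (k in seq_len(cfg$n_control_constructs))
    add(sprintf("%s_%s_c%d", ctl, ctl, k), paste(ctl, ctl, sep = ";"),
        "control", 0)

  constructs <- do.call(rbind, rows)
  rownames(constructs) <- NULL
  noise <- rnorm(nrow(constructs), 0,
                 cfg$noise_sd * cfg$platform_fidelity)
  constructs$true_lfc <- constructs$true_lfc + noise

  manifest <- data.frame(construct_id = constructs$construct_id,
                         targets = constructs$targets,
                         class = constructs$class,
                         study_id = study_id, cell_line = cell_line,
                         stringsAsFactors = FALSE)
  n <- nrow(constructs)
  ref <- if (cfg$dispersion > 0)
    rlnorm(n, log(cfg$reference_depth) - 0.125, 0.5)
  else rep(cfg$reference_depth, n)
  mu <- ref * 2^constructs$true_lfc
  counts <- matrix(0, n, 1 + cfg$replicates)
  counts[, 1] <- ref
  for (r in seq_len(cfg$replicates)) {
    counts[, 1 + r] <- if (cfg$dispersion > 0)
      rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    else mu
  }
  colnames(counts) <- c("plasmid", sprintf("T18_rep%d",
                                           seq_len(cfg$replicates)))
  rownames(counts) <- constructs$construct_id
  samples <- data.frame(
    sample_id = colnames(counts),
    role = c("reference", rep("endpoint", cfg$replicates)),
    replicate = c(1L, seq_len(cfg$replicates)),
    timepoint = c("T0", rep("T18", cfg$replicates)),
    stringsAsFactors = FALSE)
  triples <- if (is.null(tri))
    data.frame(gene1 = character(), gene2 = character(),
               gene3 = character(), effect = numeric(),
               stringsAsFactors = FALSE) else tri
  list(counts = count_matrix(counts, manifest, samples),
       truth = list(genes = gene_truth, pairs = pairs,
                    triples = triples, constructs = constructs))
}

#' Simulate a multi-study screening campaign
#'
#' Generates `n_studies` studies of `lines_per_study` cell-line screens
#' each over a shared gene set. `universal_pairs` are planted with the
#' same interaction in every screen; each entry of `background_pairs`
#' is planted in exactly one screen (background-specific hits). Each
#' study has its own `platform_fidelity` multiplier, so studies differ
#' in replicability. Per-screen seeds are derived deterministically
#' from `seed`.
#'
#' @param n_studies,lines_per_study Campaign shape (defaults 3 x 3).
#' @param universal_dlfc,background_dlfc Planted interaction sizes.
#' @param n_universal,n_background Number of planted universal /
#'   background-specific pairs.
#' @param platform_fidelity Per-study noise multipliers (length
#'   `n_studies`).
#' @param base_cfg A [screen_sim_config()] supplying all other
#'   parameters (its `sl_pairs` and `platform_fidelity` are overridden).
#' @param seed Campaign seed.
#' @return List with `screens` (named list of [simulate_screen()]
#'   results), `screen_info` (screen to study map), and `truth`
#'   (`universal_pairs`, `background_pairs` data.frames).
#' @export
simulate_multi_study <- function(n_studies = 3, lines_per_study = 3,
                                 universal_dlfc = -2,
                                 background_dlfc = -2,
                                 n_universal = 10, n_background = 9,
                                 platform_fidelity = c(1, 1.5, 2),
                                 base_cfg = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(platform_fidelity) == n_studies)
  if (is.null(base_cfg))
    base_cfg <- screen_sim_config(n_genes = 60, seed = seed)
  set.seed(seed)
  genes <- sim_gene_names(base_cfg$n_genes)
  neutral <- genes[(round(base_cfg$n_genes *
                            base_cfg$fraction_essential) + 1):
                     base_cfg$n_genes]
  n_scr <- n_studies * lines_per_study
  need <- 2 * (n_universal + n_background)
  if (length(neutral) < need)
    stop("not enough neutral genes for the requested planted pairs; ",
         "increase n_genes", call. = FALSE)
  picked <- matrix(sample(neutral, need), nrow = 2)
  mk <- function(cols) data.frame(gene1 = pmin(picked[1, cols],
                                               picked[2, cols]),
                                  gene2 = pmax(picked[1, cols],
                                               picked[2, cols]),
                                  stringsAsFactors = FALSE)
  uni <- mk(seq_len(n_universal))
  uni$dlfc <- universal_dlfc
  bg <- if (n_background > 0)
    mk(n_universal + seq_len(n_background)) else
    data.frame(gene1 = character(), gene2 = character(),
               stringsAsFactors = FALSE)
  if (n_background > 0) {
    bg$dlfc <- background_dlfc
    bg$screen <- sprintf("study%d_line%d",
                         rep(seq_len(n_studies),
                             each = lines_per_study),
                         rep(seq_len(lines_per_study), n_studies))[
                           (seq_len(n_background) - 1) %% n_scr + 1]
  } else bg$screen <- character()

  screens <- list()
  info <- list()
  for (s in seq_len(n_studies)) {
    for (l in seq_len(lines_per_study)) {
      sid <- sprintf("study%d", s)
      scr <- sprintf("study%d_line%d", s, l)
      planted <- rbind(uni[, c("gene1", "gene2", "dlfc")],
                       bg[bg$screen == scr,
                          c("gene1", "gene2", "dlfc")])
      # assay every background pair everywhere (dlfc 0 where not planted)
      other_bg <- bg[bg$screen != scr, c("gene1", "gene2"), drop = FALSE]
      if (nrow(other_bg) > 0) {
        other_bg$dlfc <- 0
        planted <- rbind(planted, other_bg)
      }
      cfg <- base_cfg
      cfg$sl_pairs <- planted
      cfg$platform_fidelity <- platform_fidelity[s]
      cfg$seed <- as.integer((seed * 1009L + s * 101L + l) %% 2147483647L)
      screens[[scr]] <- simulate_screen(cfg, study_id = sid,
                                        cell_line = scr)
      info[[scr]] <- data.frame(screen_id = scr, study_id = sid,
                                cell_line = scr,
                                stringsAsFactors = FALSE)
    }
  }
  list(screens = screens, screen_info = do.call(rbind, info),
       truth = list(universal_pairs = uni, background_pairs = bg))
}

#' Configuration for a simulated 7-guide titration screen
#'
#' @param beta_true Length-7 vector of per-guide essential knockout
#'   effects (log2 units).
#' @param position_attenuation Length-7 multipliers on the effect of a
#'   guide expressed at each position; the default leaves positions 1-5
#'   at full efficacy and attenuates positions 6 and 7, emulating the
#'   position-specific loss of editing seen late in long arrays.
#' @param pools Number of pools (default 3).
#' @param noise_sd Array-level LFC noise sd.
#' @param seed Mandatory integer seed.
#' @return A `sevenmer_sim_config` list.
#' @export
sevenmer_sim_config <- function(beta_true = c(-1.6, -2.0, -1.8, -2.2,
                                              -1.9, -2.1, -1.7),
                                position_attenuation = c(1, 1, 1, 1, 1,
                                                         0.3, 0.2),
                                pools = 3, noise_sd = 0.15, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(beta_true) == length(position_attenuation),
            all(position_attenuation >= 0 & position_attenuation <= 1),
            noise_sd >= 0, pools >= 1)
  structure(list(beta_true = beta_true,
                 position_attenuation = position_attenuation,
                 pools = pools, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sevenmer_sim_config")
}

#' Simulate a 7-guide essential/non-essential titration screen
#'
#' Array LFC = sum over essential positions of
#' `attenuation[position] * beta_true[guide]` plus Gaussian noise, over
#' the full enumeration of masks in every pool. In the forward
#' orientation the guide at position j is guide j; in the reverse
#' orientation position j carries guide n+1-j (same guides, reversed
#' order), so position attenuation and guide effect decouple in a
#' forward/reverse comparison.
#'
#' @param cfg A [sevenmer_sim_config()].
#' @param orientation `forward` or `reverse`.
#' @return An [enumerate_design()] data.frame with an `lfc` column and a
#'   `truth` attribute.
#' @export
simulate_sevenmer <- function(cfg, orientation = c("forward",
                                                   "reverse")) {
  stopifnot(inherits(cfg, "sevenmer_sim_config"))
  orientation <- match.arg(orientation)
  n <- length(cfg$beta_true)
  set.seed(cfg$seed + (orientation == "reverse"))
  design <- enumerate_design(n, cfg$pools, orientation)
  guide_at <- if (orientation == "forward") seq_len(n) else rev(seq_len(n))
  per_pos <- cfg$position_attenuation * cfg$beta_true[guide_at]
  A <- mask_to_matrix(design$mask)
  design$lfc <- as.vector(A %*% per_pos) +
    rnorm(nrow(design), 0, cfg$noise_sd)
  attr(design, "truth") <- list(beta_true = cfg$beta_true,
                                position_attenuation =
                                  cfg$position_attenuation,
                                per_position_effect = per_pos)
  design
}

random_spacers <- function(n, len = 20) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

#' Simulate paralog library-design input tables
#'
#' Generates identity, expression and guide tables with planted
#' categories whose fate under each [design_profile()] is known:
#' `n_accept` pairs inside all prototype thresholds, `n_delta_reject`
#' pairs with delta identity 15 (rejected by prototype, accepted by
#' inzolia), `n_expr_reject` pairs failing the mean-expression filter,
#' and `n_family3` three-gene groups with a top-paralog drop of 12
#' (size-2 families under prototype, size-3 under inzolia).
#'
#' @param n_accept,n_delta_reject,n_expr_reject,n_family3 Planted
#'   category sizes.
#' @param guides_per_gene Ranked guides generated per gene.
#' @param seed Mandatory integer seed.
#' @return List with `candidates`, `expression`, `guides`,
#'   `family_identities` (long gene/paralog/identity table for the
#'   planted families) and `truth` (category membership).
#' @export
simulate_design_inputs <- function(n_accept = 10, n_delta_reject = 5,
                                   n_expr_reject = 5, n_family3 = 3,
                                   guides_per_gene = 4, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  mk_genes <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  cand <- list(); expr <- list(); truth <- list()
  add_pair <- function(a, b, mid, delta, em, es, category) {
    cand[[length(cand) + 1L]] <<- data.frame(
      geneA = a, geneB = b, identity_ab = mid + delta / 2,
      identity_ba = mid - delta / 2, stringsAsFactors = FALSE)
    expr[[length(expr) + 1L]] <<- data.frame(
      gene = c(a, b), expr_mean = em, expr_std = es,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      geneA = a, geneB = b, category = category,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_accept))
    add_pair(sprintf("ACC%02dA", i), sprintf("ACC%02dB", i),
             runif(1, 40, 90), runif(1, 0, 5),
             runif(1, 3, 6), runif(1, 0.3, 1.0), "accept")
  for (i in seq_len(n_delta_reject))
    add_pair(sprintf("DEL%02dA", i), sprintf("DEL%02dB", i),
             runif(1, 40, 90), 15,
             runif(1, 3, 6), runif(1, 0.3, 1.0), "delta_reject")
  for (i in seq_len(n_expr_reject))
    add_pair(sprintf("EXP%02dA", i), sprintf("EXP%02dB", i),
             runif(1, 40, 90), runif(1, 0, 5),
             1, runif(1, 0.3, 1.0), "expr_reject")
  fam_rows <- list()
  fam_truth <- list()
  for (i in seq_len(n_family3)) {
    g <- sprintf("FAM%02d%s", i, c("A", "B", "C"))
    # A's top paralog is B at 80; C trails by a drop of 12
    fam_rows[[i]] <- data.frame(
      gene = c(g[1], g[1], g[2], g[2], g[3], g[3]),
      paralog = c(g[2], g[3], g[1], g[3], g[1], g[2]),
      identity = c(80, 68, 80, 68, 68, 68),
      stringsAsFactors = FALSE)
    fam_truth[[i]] <- data.frame(members = paste(g, collapse = ";"),
                                 drop = 12, stringsAsFactors = FALSE)
  }
  candidates <- paralog_candidates(do.call(rbind, cand))
  expression <- unique(do.call(rbind, expr))
  fam_ids <- if (n_family3 > 0) do.call(rbind, fam_rows) else
    data.frame(gene = character(), paralog = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  genes <- unique(c(candidates$geneA, candidates$geneB,
                    fam_ids$gene, fam_ids$paralog))
  guides <- data.frame(
    gene = rep(genes, each = guides_per_gene),
    rank = rep(seq_len(guides_per_gene), length(genes)),
    spacer = random_spacers(length(genes) * guides_per_gene),
    stringsAsFactors = FALSE)
  list(candidates = candidates, expression = expression,
       guides = guides, family_identities = fam_ids,
       truth = list(pairs = do.call(rbind, truth),
                    families = if (n_family3 > 0)
                      do.call(rbind, fam_truth) else NULL))
}
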