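# Small fixtures built in code.

toy_manifest <- function() {
  data.frame(
    construct_id = c("A_NT_1", "NT_A_1", "B_NT_1", "NT_B_1",
                     "A_B_1", "A_B_2", "NT_NT_1"),
    targets = c("A;NT", "NT;A", "B;NT", "NT;B", "A;B", "A;B", "NT;NT"),
    class = c("single_with_control_second", "single_with_control_first",
              "single_with_control_second", "single_with_control_first",
              "pair", "pair", "control"),
    study_id = "toy", cell_line = "toy_line",
    stringsAsFactors = FALSE)
}

toy_count_matrix <- function(counts = NULL) {
  m <- toy_manifest()
  if (is.null(counts)) {
    counts <- matrix(c(100, 200, 150, 250, 120, 130, 110,
                       100, 100, 150, 125, 30, 33, 110,
                       100, 110, 140, 130, 28, 35, 105),
                     nrow = 7,
                     dimnames = list(m$construct_id,
                                     c("plasmid", "T18_rep1",
                                       "T18_rep2")))
  }
  samples <- data.frame(
    sample_id = colnames(counts),
    role = c("reference", "endpoint", "endpoint"),
    replicate = c(1L, 1L, 2L),
    timepoint = c("T0", "T18", "T18"),
    stringsAsFactors = FALSE)
  count_matrix(counts, m, samples)
}

# fold-change table constructed directly, mean_lfc populated
toy_fc <- function(smf_a = -1, smf_b = -2, pair_lfc = NULL,
                   n_singles = 3, n_pairs = 3, jitter = 0) {
  if (is.null(pair_lfc)) pair_lfc <- smf_a + smf_b
  mk <- function(id, targets, class, val) {
    data.frame(construct_id = id, targets = targets, class = class,
               mean_lfc = val, stringsAsFactors = FALSE)
  }
  set.seed(42)
  j <- function(n) if (jitter > 0) rnorm(n, 0, jitter) else rep(0, n)
  rbind(
    mk(sprintf("A_NT_%d", 1:n_singles), "A;NT",
       "single_with_control_second", smf_a + j(n_singles)),
    mk(sprintf("NT_B_%d", 1:n_singles), "NT;B",
       "single_with_control_first", smf_b + j(n_singles)),
    mk(sprintf("A_B_%d", 1:n_pairs), "A;B", "pair",
       pair_lfc + j(n_pairs)))
}

toy_gi_table <- function(pairs, status) {
  g <- do.call(rbind, strsplit(pairs, "|", fixed = TRUE))
  data.frame(gene1 = g[, 1], gene2 = g[, 2], status = status,
             stringsAsFactors = FALSE)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}
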