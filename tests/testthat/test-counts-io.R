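test_that("count tables round-trip through TSV losslessly", {
  cm <- toy_count_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(cm, path)
  cm2 <- read_count_table(path, toy_manifest(), cm$samples)
  expect_identical(cm2$counts, cm$counts)
  expect_identical(cm2$manifest$construct_id, cm$manifest$construct_id)
})

test_that("count table validation catches structural errors", {
  m <- toy_manifest()
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(construct_id = c("A_NT_1", "ghost"),
                    s1 = c(10L, 30L), s2 = c(20L, 40L))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_count_table(path, m), "ghost")
  dup <- m; dup$construct_id[2] <- dup$construct_id[1]
  expect_error(validate_manifest(dup), "duplicated")
  bad <- m; bad$spacers <- c("ACGTACGTACGTACGTACGT;ACGTACGTACGTACGTACG",
                             rep("", 6))
  expect_error(validate_manifest(bad), "spacer")
  expect_error(count_matrix(matrix(1, 1, 1,
                                   dimnames = list("A_NT_1", "s1")),
                            m[1, ],
                            data.frame(sample_id = "s1",
                                       role = "endpoint",
                                       replicate = 1L,
                                       timepoint = "T18")),
               "reference")
})

test_that("a simple TSV reads back the integers it contains", {
  m <- toy_manifest()[1:2, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(construct_id = m$construct_id,
                         plasmid = c(10L, 30L), T18_rep1 = c(20L, 40L)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- read_count_table(path, m)
  expect_equal(unname(cm$counts),
               matrix(c(10, 30, 20, 40), nrow = 2))
  expect_equal(cm$samples$role, c("reference", "endpoint"))
})

test_that("match specs derive the matched-region length", {
  expect_equal(seven_mer_match_spec()$matched_region_length, 281L)
  expect_equal(in4mer_match_spec()$matched_region_length, 140L)
  expect_equal(match_spec(2, 23, 20)$matched_region_length, 66L)
})

test_that("exact-match counting credits only verbatim containment", {
  set.seed(7)
  spec <- match_spec(2, 10, 5)
  lib <- data.frame(construct_id = c("c1", "c2"),
                    sequence = random_dna(2, spec$matched_region_length),
                    stringsAsFactors = FALSE)
  flank <- function() random_dna(1, 15)
  reads <- c(paste0(flank(), lib$sequence[1], flank()),
             paste0(flank(), lib$sequence[2], flank()))
  # one substitution inside the matched region gets no credit
  mut <- lib$sequence[1]
  substr(mut, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 12, 12))[1]
  reads <- c(reads, paste0(flank(), mut, flank()))
  counts <- count_exact_matches(reads, lib, spec)
  expect_equal(unname(counts[c("c1", "c2")]), c(1L, 1L), ignore_attr = TRUE)
  expect_equal(attr(counts, "n_reads"), 3L)
  expect_error(count_exact_matches(reads,
                                   data.frame(construct_id = "bad",
                                              sequence = "ACGT"),
                                   spec),
               "wrong length")
})

test_that("counting recovers a generated read multiset exactly", {
  set.seed(11)
  spec <- match_spec(3, 8, 4)
  lib <- data.frame(construct_id = sprintf("c%d", 1:6),
                    sequence = random_dna(6, spec$matched_region_length),
                    stringsAsFactors = FALSE)
  truth <- c(5L, 0L, 3L, 1L, 7L, 2L)
  reads <- unlist(lapply(seq_along(truth), function(i)
    replicate(truth[i],
              paste0(random_dna(1, 10), lib$sequence[i],
                     random_dna(1, 10)))))
  reads <- sample(reads)
  counts <- count_exact_matches(reads, lib, spec)
  expect_equal(unname(counts), truth, ignore_attr = TRUE)
  expect_lte(sum(counts), length(reads))
})

test_that("multi-matching reads are credited to none and reported", {
  spec <- match_spec(1, 8, 0)
  lib <- data.frame(construct_id = c("c1", "c2"),
                    sequence = c("ACGTACGT", "GGGGCCCC"),
                    stringsAsFactors = FALSE)
  read <- paste0("TT", lib$sequence[1], "AA", lib$sequence[2], "TT")
  expect_warning(counts <- count_exact_matches(read, lib, spec),
                 "more than one")
  expect_equal(unname(counts), c(0L, 0L), ignore_attr = TRUE)
  expect_equal(attr(counts, "multi_matched"), 1L)
})

test_that("reverse-complement scanning is opt-in", {
  spec <- match_spec(1, 10, 0)
  lib <- data.frame(construct_id = "c1", sequence = "ACGTTTCAGG",
                    stringsAsFactors = FALSE)
  rc_read <- paste0("AA",
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(lib$sequence))), "AA")
  expect_equal(unname(count_exact_matches(rc_read, lib, spec)), 0L, ignore_attr = TRUE)
  expect_equal(unname(count_exact_matches(rc_read, lib, spec,
                                          scan_reverse_complement = TRUE)),
               1L, ignore_attr = TRUE)
})

test_that("fastq reading feeds the counter (gzipped too)", {
  spec <- match_spec(1, 12, 0)
  lib <- data.frame(construct_id = "c1",
                    sequence = "ACGTACGTACGT", stringsAsFactors = FALSE)
  fq <- withr::local_tempfile(fileext = ".fq.gz")
  con <- gzfile(fq, "w")
  writeLines(c("@r1", paste0("TT", lib$sequence, "GG"), "+",
               strrep("I", 16),
               "@r2", strrep("A", 16), "+", strrep("I", 16)), con)
  close(con)
  reads <- read_fastq_sequences(fq)
  expect_length(reads, 2)
  expect_equal(unname(count_exact_matches(reads, lib, spec)), 1L, ignore_attr = TRUE)
})

test_that("fold-change tables round-trip at 6-decimal precision", {
  fc <- toy_fc(jitter = 0.2)
  fc$`lfc.T18_rep1` <- fc$mean_lfc + 0.1234567
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fold_change_table(fc, path)
  back <- read_fold_change_table(path)
  expect_equal(back$mean_lfc, fc$mean_lfc, tolerance = 1e-6)
  expect_equal(back$`lfc.T18_rep1`, fc$`lfc.T18_rep1`, tolerance = 1e-6)
  # empty table writes a header-only file
  write_fold_change_table(fc[0, ], path)
  expect_equal(nrow(read_fold_change_table(path)), 0)
  expect_equal(length(readLines(path)), 1)
})

test_that("gene lists skip blanks and comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# reference set", "POLR2A", "", "  RPL3  "), path)
  expect_equal(read_gene_list(path), c("POLR2A", "RPL3"))
})
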