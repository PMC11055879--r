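test_that("candidate identity derivations are exact", {
  cand <- paralog_candidates(data.frame(
    geneA = "A", geneB = "B", identity_ab = 60, identity_ba = 50))
  expect_equal(cand$mean_identity, 55)
  expect_equal(cand$delta_identity, 10)
  expect_error(paralog_candidates(data.frame(
    geneA = "A", geneB = "B", identity_ab = 120, identity_ba = 50)),
    "identities")
})

test_that("pair selection applies profile filters with strict bounds", {
  expr <- data.frame(gene = c("A", "B"), expr_mean = 3, expr_std = 1.0)
  ok <- paralog_candidates(data.frame(geneA = "A", geneB = "B",
                                      identity_ab = 57.5,
                                      identity_ba = 52.5))
  out <- select_pairs(ok, expr, design_profile("prototype"))
  expect_true(out$accepted)

  # delta exactly at the threshold is rejected (strict <) under the
  # prototype profile, accepted under inzolia (filter disabled)
  edge <- paralog_candidates(data.frame(geneA = "A", geneB = "B",
                                        identity_ab = 60,
                                        identity_ba = 50))
  expect_false(select_pairs(edge, expr,
                            design_profile("prototype"))$accepted)
  expect_equal(select_pairs(edge, expr,
                            design_profile("prototype"))$reject_reason,
               "delta_identity")
  expect_true(select_pairs(edge, expr,
                           design_profile("inzolia"))$accepted)

  # identity band is strict on both sides for the prototype; inzolia
  # keeps only the lower bound
  hi <- paralog_candidates(data.frame(geneA = "A", geneB = "B",
                                      identity_ab = 99.5,
                                      identity_ba = 99.5))
  expect_false(select_pairs(hi, expr,
                            design_profile("prototype"))$accepted)
  expect_true(select_pairs(hi, expr,
                           design_profile("inzolia"))$accepted)

  # expression filters: mean strict >2 both genes; sd <1.5 prototype only
  lowe <- data.frame(gene = c("A", "B"), expr_mean = c(3, 2),
                     expr_std = 1.0)
  expect_false(select_pairs(ok, lowe,
                            design_profile("prototype"))$accepted)
  wob <- data.frame(gene = c("A", "B"), expr_mean = 3,
                    expr_std = c(1.0, 2.0))
  expect_false(select_pairs(ok, wob,
                            design_profile("prototype"))$accepted)
  expect_true(select_pairs(ok, wob,
                           design_profile("inzolia"))$accepted)
  # missing expression rejects with a reason, not an error
  miss <- select_pairs(ok, lowe[1, , drop = FALSE],
                       design_profile("prototype"))
  expect_equal(miss$reject_reason, "expression_missing")
})

test_that("disabling every filter passes all candidates through", {
  set.seed(12)
  cand <- paralog_candidates(data.frame(
    geneA = sprintf("A%02d", 1:20), geneB = sprintf("B%02d", 1:20),
    identity_ab = runif(20, 5, 99), identity_ba = runif(20, 5, 99)))
  expr <- data.frame(gene = c(cand$geneA, cand$geneB),
                     expr_mean = runif(40, 0, 8),
                     expr_std = runif(40, 0, 3))
  open_profile <- design_profile("inzolia")
  open_profile$identity_min <- -Inf
  open_profile$expr_mean_min <- -Inf
  out <- select_pairs(cand, expr, open_profile)
  expect_true(all(out$accepted))
})

test_that("family clustering follows the difference-from-top-paralog rule", {
  # B at 80, C at 75: drop 5 joins under both profiles
  ids <- data.frame(gene = c("A", "A", "B", "B", "C", "C"),
                    paralog = c("B", "C", "A", "C", "A", "B"),
                    identity = c(80, 75, 80, 75, 75, 75))
  fam <- cluster_families(ids, design_profile("prototype"))
  expect_equal(fam, list(c("A", "B", "C")))
  # drop 15: size-2 family under prototype, size-3 under inzolia
  ids$identity <- c(80, 65, 80, 65, 65, 65)
  expect_equal(cluster_families(ids, design_profile("prototype")),
               list(c("A", "B")))
  expect_equal(cluster_families(ids, design_profile("inzolia")),
               list(c("A", "B", "C")))
})

test_that("oversized components truncate to four members deterministically", {
  genes <- sprintf("F%d", 1:6)
  rows <- list()
  for (g in genes) {
    others <- setdiff(genes, g)
    rows[[g]] <- data.frame(gene = g, paralog = others,
                            identity = c(80, 79, 78, 77, 76),
                            stringsAsFactors = FALSE)
  }
  ids <- do.call(rbind, rows)
  fam <- cluster_families(ids, design_profile("prototype"))
  # the first anchor keeps its three smallest-drop partners; the two
  # leftover genes pair with each other
  expect_length(fam[[1]], 4)
  expect_equal(fam[[1]], sprintf("F%d", 1:4))
  expect_true(all(lengths(fam) <= 4))
  expect_identical(fam, cluster_families(ids, design_profile("prototype")))
})

test_that("arrays follow the sibling scheme for each target class", {
  guides <- data.frame(
    gene = rep(c("A", "B", "C", "D", "E", "F", "G"), each = 4),
    rank = rep(1:4, 7),
    spacer = random_dna(28, 20), stringsAsFactors = FALSE)
  pads <- data.frame(gene = "NE1", rank = 1:2,
                     spacer = random_dna(2, 20),
                     stringsAsFactors = FALSE)
  arr <- build_arrays(singles = "A",
                      families = list(c("B", "C"), c("D", "E", "F")),
                      guides = guides, pad_guides = pads)
  expect_equal(nrow(arr), 6)
  # singles: same guide multiset, different order
  s <- arr[arr$class == "single", ]
  sp <- strsplit(s$spacers, ";")
  expect_setequal(sp[[1]], sp[[2]])
  expect_false(identical(sp[[1]], sp[[2]]))
  # pairs: two guides per gene, interleaved; same multiset across siblings
  p <- arr[arr$class == "pair", ]
  expect_equal(strsplit(p$slot_targets[1], ";")[[1]],
               c("B", "C", "B", "C"))
  expect_setequal(strsplit(p$spacers, ";")[[1]],
                  strsplit(p$spacers, ";")[[2]])
  # triples: one guide per gene plus pad; siblings disjoint
  t3 <- arr[arr$class == "triple", ]
  tsp <- strsplit(t3$spacers, ";")
  expect_length(intersect(tsp[[1]], tsp[[2]]), 0)
  expect_equal(strsplit(t3$slot_targets[1], ";")[[1]][4], "NE1")
  # insufficient guides named in the error
  expect_error(build_arrays(singles = "G",
                            guides = guides[guides$rank <= 3, ]),
               "G")
})

test_that("oligo assembly matches the printed template byte for byte", {
  sp <- random_dna(4, 20)
  o <- assemble_oligo(sp, "arr1", "prototype")
  expect_equal(nchar(o$sequence), 212)
  expect_equal(sum(o$segment_map$length), 212)
  dr <- internal_dr_sequences()
  expected <- paste0("AATGATACGGCGACCACCGA", "cgtctcgAGAT",
                     sp[1], dr[1], sp[2], dr[2], sp[3], dr[3], sp[4],
                     "TTTTTT", "GAATggagacg",
                     "ATCTCGTATGCCGTCTTCTGCTTG")
  expect_identical(o$sequence, expected)
  o2 <- assemble_oligo(sp, "arr1", "inzolia")
  expect_equal(nchar(o2$sequence), 208)
  expect_identical(substr(o2$sequence, 1, 20), "AGGCACTTGCTCGTACGACG")
  expect_identical(substr(o2$sequence, 189, 208),
                   "TTAAGGTGCCGGGCCCACAT")
  # DRs at the offsets the segment map declares, once each
  for (i in 1:3) {
    seg <- o$segment_map[o$segment_map$segment ==
                           c("dr_a", "dr_b", "dr_c")[i], ]
    expect_identical(substr(o$sequence, seg$start, seg$end), dr[i])
    expect_equal(lengths(gregexpr(dr[i], o$sequence, fixed = TRUE)), 1L)
  }
  # BsmBI recognition core appears on both restriction segments
  rs <- o$segment_map[o$segment_map$segment %in%
                        c("restriction5", "restriction3"), "sequence"]
  expect_true(all(grepl("cgtctc|ggagac",
                        vapply(rs, tolower, ""))))
  expect_error(assemble_oligo(c(sp[1:3], "ACGT")), "20 nt")
  expect_error(assemble_oligo(c(sp[1:3], strrep("N", 20))), "ACGT")
})

test_that("assembly is injective on distinct spacer tuples", {
  set.seed(13)
  tuples <- replicate(500, random_dna(4, 20), simplify = FALSE)
  tuples <- unique(tuples)
  seqs <- vapply(tuples, function(sp) assemble_oligo(sp)$sequence, "")
  expect_equal(anyDuplicated(seqs), 0L)
})

test_that("library accounting reproduces the published manifests", {
  proto <- library_accounting(n_singles = 19687, n_pairs = 2082,
                              n_triples = 167, n_quads = 48,
                              n_control_arrays = 4)
  expect_equal(proto$total, 43972)
  inz <- library_accounting(n_singles = 19687, n_pairs = 4435,
                            n_triples = 376, n_quads = 100,
                            n_control_arrays = 20 + 500 + 50)
  expect_equal(inz$paralog_family_arrays, 9822)
  expect_equal(inz$control_arrays, 570)
  empty <- library_accounting()
  expect_equal(empty$total, 0)
  # six reagents per pair test: fivefold fewer than thirty
  expect_equal(reagents_per_family_test(), 6)
  expect_equal(30 / reagents_per_family_test(), 5)
})

test_that("manifest accounting checks uniqueness and counts classes", {
  guides <- data.frame(gene = rep(c("A", "B", "C"), each = 4),
                       rank = rep(1:4, 3),
                       spacer = random_dna(12, 20),
                       stringsAsFactors = FALSE)
  arr <- build_arrays(singles = "A", families = list(c("B", "C")),
                      guides = guides)
  acc <- manifest_accounting(arr, assemble_oligos(arr))
  expect_equal(acc$total, 4)
  expect_equal(unname(acc$by_class[c("single", "pair")]), c(2L, 2L))
  expect_equal(acc$paralog_family_arrays, 2)
  dup <- rbind(arr, arr[1, ])
  expect_error(manifest_accounting(dup), "duplicate")
  # sibling pair arrays share guides but in different slot order, so
  # their oligos differ; force a collision to see it caught
  ol <- assemble_oligos(arr)
  ol$sequence[2] <- ol$sequence[1]
  expect_error(manifest_accounting(arr, ol), "collision")
})

test_that("oligo FASTA writing preserves case and ids", {
  arr <- build_arrays(singles = "A",
                      guides = data.frame(gene = "A", rank = 1:4,
                                          spacer = random_dna(4, 20)))
  ol <- assemble_oligos(arr)
  path <- withr::local_tempfile(fileext = ".fa")
  write_oligo_fasta(ol, path)
  back <- Biostrings::readBStringSet(path)
  expect_equal(names(back), ol$array_id)
  expect_equal(as.character(back[[1]]), ol$sequence[1])
})
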