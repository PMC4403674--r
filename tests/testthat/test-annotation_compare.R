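mk_set <- function(ids, seqs, symbols = NA_character_) {
  data.frame(protein_id = ids, gene_id = NA_character_,
             gene_symbol = symbols, description = NA_character_,
             seq = seqs, stringsAsFactors = FALSE)
}

test_that("comparison means are arithmetic means over proteins with a hit", {
  set.seed(41)
  ref_seq <- paste0("M", rand_aa(99))
  reference <- seq_records("R1", ref_seq)
  # identical (100% identity, 0 gaps) and 2-residue deletion (gaps 2)
  del <- paste0(substr(ref_seq, 1, 40), substr(ref_seq, 43, 100))
  set <- mk_set(c("a", "b", "c"), c(ref_seq, del, rand_aa(100)),
                c("GA", "GB", "GC"))
  res <- compare_to_reference(set, reference, min_score = 200)
  expect_equal(res$n_proteins, 3L)
  expect_equal(res$n_with_hit, 2L)  # the random protein has no hit
  per <- res$per_protein
  expect_equal(per$pct_identity[per$protein_id == "a"], 100)
  expect_equal(per$gaps[per$protein_id == "b"], 2L)
  expect_equal(res$mean_pct_identity, mean(per$pct_identity))
  expect_equal(res$mean_gaps, mean(per$gaps))
  expect_true(all(per$pct_identity <= per$pct_similarity))
  expect_error(compare_to_reference(set[0L, ], reference), "empty")
})

test_that("a set compared against itself scores perfect identity", {
  set.seed(42)
  seqs <- vapply(1:5, function(i) paste0("M", rand_aa(59)), character(1L))
  set <- mk_set(sprintf("p%d", 1:5), seqs, sprintf("G%d", 1:5))
  res <- compare_to_reference(set, seq_records(sprintf("r%d", 1:5), seqs))
  expect_equal(res$n_with_hit, 5L)
  expect_equal(res$mean_pct_identity, 100)
  expect_equal(res$mean_pct_similarity, 100)
  expect_equal(res$mean_gaps, 0)
})

test_that("filter_by_symbol keeps exactly the entries with a symbol", {
  set <- mk_set(c("a", "b", "c"), c("MA", "MC", "MD"),
                c("G1", "", NA))
  expect_equal(filter_by_symbol(set)$protein_id, "a")
  all_sym <- mk_set(c("a", "b"), c("MA", "MC"), c("G1", "G2"))
  expect_equal(filter_by_symbol(all_sym), all_sym)
  none <- mk_set(c("a", "b"), c("MA", "MC"), c("", ""))
  expect_equal(nrow(filter_by_symbol(none)), 0L)
})

test_that("filter-then-compare equals compare-then-subset", {
  set.seed(43)
  ref_seqs <- vapply(1:6, function(i) paste0("M", rand_aa(49)),
                     character(1L))
  reference <- seq_records(sprintf("r%d", 1:6), ref_seqs)
  set <- mk_set(sprintf("p%d", 1:6), ref_seqs,
                c("G1", "", "G3", NA, "G5", "G6"))
  direct <- compare_to_reference(filter_by_symbol(set), reference)
  full <- compare_to_reference(set, reference)
  sub <- full$per_protein[full$per_protein$protein_id %in%
                            filter_by_symbol(set)$protein_id, ]
  expect_equal(direct$mean_pct_identity, mean(sub$pct_identity))
  expect_equal(direct$mean_gaps, mean(sub$gaps))
})

test_that("single-isoform overlap restricts to shared listed genes", {
  per_a <- data.frame(protein_id = c("a1", "a2", "a3", "a4"),
                      gene_symbol = c("X", "Y", "Z", "Y"),
                      subject_id = "r", pct_identity = c(95, 90, 88, 97),
                      pct_similarity = c(96, 92, 90, 98),
                      gaps = 0L, gap_opens = 0L, stringsAsFactors = FALSE)
  per_b <- data.frame(protein_id = c("b1", "b2", "b3"),
                      gene_symbol = c("Y", "Z", "W"),
                      subject_id = "r", pct_identity = c(80, 85, 99),
                      pct_similarity = c(82, 88, 99),
                      gaps = c(2L, 1L, 0L), gap_opens = 1L,
                      stringsAsFactors = FALSE)
  sum_a <- transannot:::.comparison_summary(4L, per_a)
  sum_b <- transannot:::.comparison_summary(3L, per_b)
  ov <- single_isoform_overlap(sum_a, sum_b, c("Y"))
  expect_equal(ov$genes, "Y")
  # gene Y has two rows in A (90, 97): the best-identity row represents it
  expect_equal(ov$summary_a$per_protein$pct_identity, 97)
  expect_equal(ov$summary_b$per_protein$pct_identity, 80)
  # empty intersection is not an error
  ov0 <- single_isoform_overlap(sum_a, sum_b, character())
  expect_equal(ov0$genes, character())
  expect_equal(ov0$summary_a$n_with_hit, 0L)
  # identical sets: overlap = single-isoform genes present in the set
  ov2 <- single_isoform_overlap(sum_a, sum_a, c("X", "Z", "Q"))
  expect_equal(ov2$genes, c("X", "Z"))
})

test_that("missing_genes is asymmetric set difference on with-hit symbols", {
  per_b <- data.frame(protein_id = "b1", gene_symbol = "G2",
                      subject_id = "r", pct_identity = 90,
                      pct_similarity = 91, gaps = 0L, gap_opens = 0L,
                      stringsAsFactors = FALSE)
  sum_b <- transannot:::.comparison_summary(1L, per_b)
  expect_equal(missing_genes(c("G1", "G2", "G3"), sum_b), c("G1", "G3"))
  expect_equal(missing_genes(c("G2"), sum_b), character())
  expect_equal(missing_genes(character(), sum_b), character())
  expect_equal(missing_genes(c("G3", "G1", "G3", ""), sum_b),
               c("G1", "G3"))
})

test_that("restricting to an overlap cannot move means outside the row range", {
  set.seed(44)
  ref_seqs <- vapply(1:8, function(i) paste0("M", rand_aa(59)),
                     character(1L))
  reference <- seq_records(sprintf("r%d", 1:8), ref_seqs)
  noisy <- vapply(ref_seqs, function(s) {
    aa <- strsplit(s, "")[[1L]]
    k <- sample(2:60, 3L)
    aa[k] <- sample(c("A", "G", "V"), 3L, replace = TRUE)
    paste(aa, collapse = "")
  }, character(1L))
  set_a <- mk_set(sprintf("a%d", 1:8), ref_seqs, sprintf("G%d", 1:8))
  set_b <- mk_set(sprintf("b%d", 1:8), noisy, sprintf("G%d", 1:8))
  sum_a <- compare_to_reference(set_a, reference)
  sum_b <- compare_to_reference(set_b, reference)
  ov <- single_isoform_overlap(sum_a, sum_b, sprintf("G%d", 1:4))
  for (s in list(ov$summary_a, ov$summary_b)) {
    full <- if (identical(s, ov$summary_a)) sum_a else sum_b
    expect_gte(s$mean_pct_identity, min(full$per_protein$pct_identity))
    expect_lte(s$mean_pct_identity, max(full$per_protein$pct_identity))
  }
})
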