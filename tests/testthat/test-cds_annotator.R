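# toy transcript: GGG | ATG AAA TGC | TAA | CC ; CDS [4,12], protein MKC
toy_seq <- "GGGATGAAATGCTAACC"

toy_hit <- function(id = "t1", q_start = 7L, q_end = 12L, frame = 1L) {
  h <- mk_hit(id, 2L, score = 10, n_identical = 2L, subject_id = "P1")
  h$q_start <- q_start; h$q_end <- q_end; h$frame <- frame
  h
}

test_that("derive_cds extends a hit to the nearest in-frame start and stop", {
  # hit covers codons 2-3 (AAA TGC); extension finds ATG at 4, TAA at 13
  cand <- derive_cds(list(id = "t1", seq = toy_seq), toy_hit())
  expect_equal(cand$status, "candidate")
  expect_equal(c(cand$cds_start, cand$cds_end), c(4L, 12L))
  expect_equal(cand$protein, "MKC")
  expect_equal(cand$strand, "+")
  expect_equal(cand$stop_codon, "TAA")
})

test_that("derive_cds maps antisense hits back to forward coordinates", {
  rc <- revcomp(toy_seq)
  L <- nchar(toy_seq)
  # the same codons seen on the minus strand: forward coords swap roles
  hit <- toy_hit(q_start = L - 7L + 1L, q_end = L - 12L + 1L, frame = -1L)
  cand <- derive_cds(list(id = "t1", seq = rc), hit)
  expect_equal(cand$status, "candidate")
  expect_equal(cand$protein, "MKC")
  expect_equal(cand$strand, "-")
  expect_equal(c(cand$cds_start, cand$cds_end), c(L - 12L + 1L, L - 4L + 1L))
  # forward-strand invariant: revcomp of the CDS slice translates to MKC
  slice <- substr(rc, cand$cds_start, cand$cds_end)
  expect_equal(translate_frame(revcomp(slice), 1L), "MKC")
})

test_that("derive_cds rejects transcripts missing start, stop, or with internal stops", {
  # no ATG upstream of the hit before the sequence edge
  no_start <- paste0("AAATGC", "TAACC")  # codons AAA TGC TAA
  cand <- derive_cds(list(id = "t", seq = no_start),
                     toy_hit("t", 1L, 6L))
  expect_equal(cand$reason, "no_start")
  # in-frame stop upstream of the hit blocks the ATG beyond it
  blocked <- paste0("ATG", "TAA", "AAATGC", "TAACC")
  cand <- derive_cds(list(id = "t", seq = blocked), toy_hit("t", 7L, 12L))
  expect_equal(cand$reason, "no_start")
  no_stop <- "GGGATGAAATGCCC"  # no in-frame stop downstream
  cand <- derive_cds(list(id = "t", seq = no_stop), toy_hit("t", 7L, 12L))
  expect_equal(cand$reason, "no_stop")
  with_stop <- "GGGATGTAATGCTAACC"  # aligned range includes TAA
  cand <- derive_cds(list(id = "t", seq = with_stop), toy_hit("t", 4L, 12L))
  expect_equal(cand$reason, "internal_stop")
  expect_error(derive_cds(list(id = "t", seq = toy_seq),
                          toy_hit("t", frame = 0L)), "translated")
  expect_error(derive_cds(list(id = "other", seq = toy_seq), toy_hit()),
               "does not match")
})

test_that("extend = FALSE takes the literal hit range only", {
  tr <- list(id = "t1", seq = toy_seq)
  lit <- derive_cds(tr, toy_hit(q_start = 4L, q_end = 12L), extend = FALSE)
  expect_equal(lit$status, "candidate")
  expect_equal(c(lit$cds_start, lit$cds_end), c(4L, 12L))
  expect_equal(derive_cds(tr, toy_hit(), extend = FALSE)$reason, "no_start")
})

test_that("validation applies inclusive identity and length-difference thresholds", {
  set.seed(31)
  ort_seq <- paste0("M", rand_aa(99))
  ort <- seq_records("P1", ort_seq, gene_symbol = "G1")
  mk_cand <- function(protein) {
    list(status = "candidate", cds_start = 1L,
         cds_end = 3L * nchar(protein), strand = "+", frame = 1L,
         protein = protein, stop_codon = "TAA")
  }
  ann <- validate_annotation(mk_cand(ort_seq), "t1", ort)
  expect_equal(ann$status, "accepted")
  expect_equal(ann$pct_identity, 100)
  expect_equal(ann$length_diff, 0L)
  expect_equal(ann$gene_symbol, "G1")
  # protein = first 90 residues: identity 100%, length_diff 10 -> accepted
  ann <- validate_annotation(mk_cand(substr(ort_seq, 1, 90)), "t1", ort)
  expect_equal(ann$status, "accepted")
  expect_equal(ann$length_diff, 10L)
  ann <- validate_annotation(mk_cand(substr(ort_seq, 1, 89)), "t1", ort)
  expect_equal(ann$reject_reason, "length_diff_above")
  expect_error(validate_annotation(mk_cand(ort_seq), "t1", ort,
                                   min_identity = -1), "non-negative")
  # structural rejections pass through with their reason
  ann <- validate_annotation(list(status = "rejected", reason = "no_stop"),
                             "t1", ort)
  expect_equal(ann$reject_reason, "no_stop")
})

test_that("identity exactly at the threshold is accepted, below is rejected", {
  set.seed(32)
  ort_seq <- paste0("M", rand_aa(99))
  ort <- seq_records("P1", ort_seq, gene_symbol = "G1")
  mutate_at <- function(seq, pos) {
    aa <- strsplit(seq, "")[[1L]]
    for (p in pos) aa[p] <- setdiff(c("A", "G"), aa[p])[1L]
    paste(aa, collapse = "")
  }
  # 15 interior substitutions over 100 columns -> exactly 85% identity
  pos <- seq(5L, 95L, length.out = 15L)
  p85 <- mutate_at(ort_seq, round(pos))
  cand <- list(status = "candidate", cds_start = 1L, cds_end = 300L,
               strand = "+", frame = 1L, protein = p85, stop_codon = "TAA")
  ann <- validate_annotation(cand, "t1", ort)
  expect_equal(ann$pct_identity, 85)
  expect_equal(ann$status, "accepted")
  # one more substitution (at a previously untouched position) -> 84%
  p84 <- mutate_at(p85, 52L)
  cand$protein <- p84
  ann <- validate_annotation(cand, "t1", ort)
  expect_equal(ann$pct_identity, 84)
  expect_equal(ann$reject_reason, "identity_below")
})

test_that("annotate_transcripts tallies unique proteins, genes and reject reasons", {
  set.seed(33)
  prot_a <- paste0("M", rand_aa(59))
  prot_b <- paste0("M", rand_aa(49))
  orthologs <- seq_records(c("P1", "P2"), c(prot_a, prot_b),
                           gene_symbol = c("G1", "G2"))
  mk_tr <- function(protein) {
    # ATG-free UTRs so the derived CDS is exactly the encoded one
    paste0(strrep("C", 12), first_codon_cds(protein), "TAA", strrep("C", 9))
  }
  transcripts <- seq_records(
    c("t1", "t2", "t3", "decoy1"),
    c(mk_tr(prot_a), mk_tr(prot_a), mk_tr(prot_b), rand_dna(150)))
  res <- annotate_transcripts(transcripts, orthologs, min_hit_score = 100)
  expect_equal(res$summary$n_transcripts, 4L)
  expect_equal(res$summary$n_annotated, 3L)
  expect_equal(res$summary$n_unique_proteins, 2L)
  expect_equal(res$summary$n_unique_genes, 2L)
  expect_equal(unname(res$summary$rejects_by_reason["no_hit"]), 1L)
  # empty input gives an all-zero summary
  empty <- annotate_transcripts(transcripts[0L, ], orthologs)
  expect_equal(empty$summary$n_transcripts, 0L)
  expect_equal(empty$summary$n_annotated, 0L)
  expect_error(
    annotate_transcripts(transcripts, orthologs[, c("id", "seq")]),
    "gene_symbol")
})

test_that("accepted annotations are internally consistent and written faithfully", {
  cfg <- sim_config(seed = 5, n_genes = 8, protein_len_range = c(40, 80),
                    frac_decoy = 0.25, frac_truncated = 0)
  pr <- simulate_proteome(cfg)
  tr <- simulate_transcripts(pr, cfg)
  res <- annotate_transcripts(tr$transcripts, pr$proteins)
  acc <- res$annotations[res$annotations$status == "accepted", ]
  expect_gt(nrow(acc), 0L)
  for (i in seq_len(nrow(acc))) {
    seq <- tr$transcripts$seq[tr$transcripts$id == acc$transcript_id[i]]
    expect_equal((acc$cds_end[i] - acc$cds_start[i] + 1L) %% 3L, 0L)
    cds <- substr(seq, acc$cds_start[i], acc$cds_end[i])
    if (acc$strand[i] == "-") cds <- revcomp(cds)
    expect_equal(translate_frame(cds, 1L), acc$protein[i])
    expect_match(acc$protein[i], "^M")
    expect_false(grepl("*", acc$protein[i], fixed = TRUE))
    # the codon after the CDS on the reading strand is a stop
    stop_cod <- if (acc$strand[i] == "-") {
      revcomp(substr(seq, acc$cds_start[i] - 3L, acc$cds_start[i] - 1L))
    } else {
      substr(seq, acc$cds_end[i] + 1L, acc$cds_end[i] + 3L)
    }
    expect_true(stop_cod %in% c("TAA", "TAG", "TGA"))
  }
  out <- withr::local_tempdir()
  paths <- write_annotations(res, file.path(out, "ann"))
  fa <- read_fasta(paths[["proteins"]])
  expect_equal(nrow(fa), nrow(acc))
  expect_equal(sort(fa$seq), sort(acc$protein))
  rej <- read.delim(paths[["rejects"]])
  expect_equal(nrow(rej), sum(res$annotations$status == "rejected"))
})

test_that("relaxing thresholds never decreases the annotated count", {
  cfg <- sim_config(seed = 6, n_genes = 10, protein_len_range = c(40, 80),
                    substitution_rate = 0.12, frac_decoy = 0,
                    frac_truncated = 0)
  pr <- simulate_proteome(cfg)
  tr <- simulate_transcripts(pr, cfg)
  n_ann <- function(min_id, max_ld) {
    annotate_transcripts(tr$transcripts, pr$proteins,
                         min_identity = min_id,
                         max_length_diff = max_ld)$summary$n_annotated
  }
  strict <- n_ann(85, 10)
  looser_id <- n_ann(70, 10)
  looser_ld <- n_ann(85, 30)
  expect_gte(looser_id, strict)
  expect_gte(looser_ld, strict)
})
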