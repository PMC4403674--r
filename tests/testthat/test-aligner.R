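nt_scoring <- default_scoring()$nt

test_that("exact and near-exact nucleotide matches are reported faithfully", {
  set.seed(101)
  subj_seq <- rand_dna(400)
  q <- substr(subj_seq, 120, 220)  # 101 nt exact substring
  hit <- align_local_nt(list(id = "r1", seq = q),
                        seq_records("s1", subj_seq))
  expect_equal(hit$alignment_length, 101L)
  expect_equal(hit$pct_identity, 100)
  expect_equal(hit$n_gap_chars, 0L)
  expect_equal(c(hit$s_start, hit$s_end), c(120L, 220L))
  expect_equal(c(hit$q_start, hit$q_end), c(1L, 101L))

  q2 <- q
  substr(q2, 50, 50) <- chartr("ACGT", "TGCA", substr(q2, 50, 50))
  hit2 <- align_local_nt(list(id = "r2", seq = q2),
                         seq_records("s1", subj_seq))
  expect_equal(hit2$alignment_length, 101L)
  expect_equal(hit2$n_identical, 100L)
  # a 100-column perfect flank: 99/100 identity when trimmed to it
  sub100 <- substr(q2, 1, 100)
  hit3 <- align_local_nt(list(id = "r3", seq = sub100),
                         seq_records("s1", subj_seq))
  expect_equal(hit3$n_identical, 99L)
  expect_equal(round(hit3$pct_identity, 1), 99.0)
})

test_that("score ties break by identical count then subject id", {
  q <- "ACGTACGTACGT"
  subjects <- seq_records(c("zz", "aa"), c(q, q))
  hit <- align_local_nt(list(id = "q", seq = q), subjects)
  expect_equal(hit$subject_id, "aa")
  expect_null(align_local_nt(list(id = "q", seq = ""), subjects))
  expect_null(align_local_nt(list(id = "q", seq = q), subjects[0L, ]))
})

test_that("translated alignment finds frames and maps coordinates to the strand", {
  # codons of MKLV, preceded by a 7-nt UTR
  cds <- "ATGAAACTGGTG"
  q <- paste0("GCCGCCA", cds)
  subj <- seq_records("P1", "MKLV")
  hit <- align_translated(list(id = "t", seq = q), subj)
  expect_equal(hit$frame, 2L)  # offset 7 => frame +2
  expect_equal(hit$pct_identity, 100)
  expect_equal(hit$q_start, 8L)
  expect_equal(hit$q_end, 8L + 3L * 4L - 1L)
  # reverse complement: negative frame, q_start > q_end on forward coords
  qrc <- revcomp(q)
  hit_rc <- align_translated(list(id = "t", seq = qrc), subj)
  expect_lt(hit_rc$frame, 0L)
  expect_gt(hit_rc$q_start, hit_rc$q_end)
  expect_equal(hit_rc$pct_identity, 100)
  L <- nchar(q)
  expect_equal(hit_rc$q_start, L - 8L + 1L)
  expect_equal(hit_rc$q_end, L - hit$q_end + 1L)
  expect_null(align_translated(list(id = "t", seq = "AT"), subj))
})

test_that("protein alignment reports positives and honors max_targets", {
  q <- "MKLVDEWQRH"
  hits <- align_protein(list(id = "p", seq = q), seq_records("s", q))
  expect_equal(hits$pct_identity, 100)
  expect_equal(100 * hits$n_positive / hits$alignment_length, 100)
  expect_equal(hits$n_gap_chars, 0L)
  # one conservative substitution (K->R scores +2 in BLOSUM62)
  q2 <- sub("K", "R", q)
  hits2 <- align_protein(list(id = "p", seq = q2), seq_records("s", q))
  expect_equal(hits2$n_identical, nchar(q) - 1L)
  expect_equal(hits2$n_positive, nchar(q))
  # max_targets truncates a sorted hit list
  subjects <- seq_records(c("a", "b", "c"),
                          c(q, sub("K", "R", q), "WWWWWWWW"))
  all_hits <- align_protein(list(id = "p", seq = q), subjects,
                            max_targets = 3L)
  expect_equal(all_hits$subject_id[1L], "a")
  expect_true(all(diff(all_hits$score) <= 0))
  expect_equal(nrow(align_protein(list(id = "p", seq = q), subjects,
                                  max_targets = 1L)), 1L)
  expect_equal(nrow(align_protein(list(id = "p", seq = ""), subjects)), 0L)
})

test_that("gapped alignments carry gap counts consistent with their rows", {
  b62 <- ref_blosum62()
  q <- "MKLVDEWQRHAA"
  s <- "MKLVWQRHAA"  # two-residue deletion relative to q
  hit <- align_protein(list(id = "p", seq = q), seq_records("s", s))
  counts <- ref_alignment_counts(hit$aligned_query, hit$aligned_subject, b62)
  expect_equal(hit$n_gap_chars, counts$n_gap_chars)
  expect_equal(hit$n_gap_opens, counts$n_gap_opens)
  expect_equal(hit$n_identical, counts$n_identical)
  expect_gt(hit$n_gap_chars, 0L)
  expect_equal(ref_alignment_score(hit$aligned_query, hit$aligned_subject,
                                   b62, 11, 1), hit$score)
})

test_that("engines agree with the brute-force DP oracle on random instances", {
  set.seed(202)
  mat_nt <- ref_nt_matrix()
  b62 <- ref_blosum62()
  for (k in 1:20) {
    q <- rand_dna(sample(20:60, 1L))
    s <- rand_dna(sample(20:60, 1L))
    hit <- align_local_nt(list(id = "q", seq = q), seq_records("s", s),
                          min_score = 0)
    oracle <- ref_sw_score(q, s, mat_nt, 5, 2)
    expect_equal(if (is.null(hit)) 0 else hit$score, oracle)
  }
  for (k in 1:20) {
    q <- rand_aa(sample(15:60, 1L))
    s <- rand_aa(sample(15:60, 1L))
    hit <- align_protein(list(id = "q", seq = q), seq_records("s", s),
                         min_score = 1)
    oracle <- ref_sw_score(q, s, b62, 11, 1)
    expect_equal(if (nrow(hit) == 0L) 0 else hit$score, max(oracle, 0))
  }
  for (k in 1:10) {
    q <- rand_dna(sample(30:60, 1L))
    s <- rand_aa(sample(10:20, 1L))
    hit <- align_translated(list(id = "q", seq = q), seq_records("s", s))
    oracle <- ref_translated_score(q, s, b62, 11, 1)
    expect_equal(if (is.null(hit)) 0 else hit$score, max(oracle, 0))
  }
})

test_that("identity and gap counts are symmetric under query/subject swap", {
  set.seed(303)
  b62 <- ref_blosum62()
  for (k in 1:10) {
    a <- rand_aa(40)
    b <- rand_aa(40)
    h1 <- align_protein(list(id = "a", seq = a), seq_records("b", b),
                        min_score = 1)
    h2 <- align_protein(list(id = "b", seq = b), seq_records("a", a),
                        min_score = 1)
    if (nrow(h1) == 0L || nrow(h2) == 0L) {
      expect_equal(nrow(h1), nrow(h2))
      next
    }
    expect_equal(h1$score, h2$score)
    expect_equal(h1$n_identical, h2$n_identical)
    expect_equal(h1$n_gap_chars, h2$n_gap_chars)
  }
})

test_that("self-alignment dominates alignments to other sequences", {
  set.seed(404)
  s <- rand_aa(50)
  self <- align_protein(list(id = "s", seq = s), seq_records("s2", s))
  for (k in 1:5) {
    other <- align_protein(list(id = "s", seq = s),
                           seq_records("o", rand_aa(50)), min_score = 0)
    expect_gte(self$score, if (nrow(other)) other$score else 0)
  }
})

test_that("BLAST tabular parsing maps fields, infers frames and flags errors", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("t1\tP1\t100.000\t90\t0\t0\t31\t300\t1\t90\t1e-50\t180",
               "t2\tP2\t95.000\t80\t4\t1\t250\t11\t1\t80\t1e-40\t150"), p)
  hits <- parse_blast_tabular(p, mode = "translated")
  expect_equal(hits$q_start[1L], 31L)
  expect_equal(hits$q_end[1L], 300L)
  expect_equal(hits$frame[1L], 1L)
  expect_equal(hits$n_identical[1L], 90L)
  expect_equal(hits$frame[2L], -1L)  # qstart > qend
  expect_true(is.na(hits$n_positive[1L]))

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("t1\tP1\t100.000\t90\t0\t0\t31\t300\t1\t90\t1e-50", p2)
  expect_error(parse_blast_tabular(p2, "translated"), "line 1")
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("t1\tP1\tabc\t90\t0\t0\t31\t300\t1\t90\t1e-50\t180", p3)
  expect_error(parse_blast_tabular(p3, "translated"), "non-numeric")
})

test_that("writing and re-parsing a tabular file is lossless for core columns", {
  set.seed(505)
  q <- rand_aa(40)
  s <- paste0(substr(q, 1, 20), substr(q, 24, 40))
  hits <- rbind(
    align_protein(list(id = "q1", seq = q), seq_records("s1", s)),
    align_protein(list(id = "q2", seq = q), seq_records("s2", q)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tabular(hits, p, extended = TRUE)
  back <- parse_blast_tabular(p, mode = "protein")
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$subject_id, hits$subject_id)
  expect_equal(back$alignment_length, hits$alignment_length)
  expect_equal(back$n_mismatch, hits$n_mismatch)
  expect_equal(back$n_gap_opens, hits$n_gap_opens)
  expect_equal(back$q_start, hits$q_start)
  expect_equal(back$q_end, hits$q_end)
  expect_equal(back$s_start, hits$s_start)
  expect_equal(back$s_end, hits$s_end)
  expect_equal(back$pct_identity, round(hits$pct_identity, 3))
  expect_equal(back$n_positive, hits$n_positive)
  expect_equal(back$n_gap_chars, hits$n_gap_chars)
  expect_equal(back$score, hits$score)
})
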