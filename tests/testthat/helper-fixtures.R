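# Small fixture builders shared across test files.

# a minimal alignment-hit row with the fields the filter logic consumes
mk_hit <- function(query_id, alignment_length, score = alignment_length * 2,
                   n_identical = alignment_length, subject_id = "ref1") {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = 100 * n_identical / alignment_length,
             alignment_length = as.integer(alignment_length),
             n_identical = as.integer(n_identical),
             n_mismatch = 0L, n_positive = as.integer(n_identical),
             n_gap_chars = 0L, n_gap_opens = 0L,
             q_start = 1L, q_end = as.integer(alignment_length),
             s_start = 1L, s_end = as.integer(alignment_length),
             frame = 0L, score = score, evalue = NA_real_,
             aligned_query = NA_character_,
             aligned_subject = NA_character_, stringsAsFactors = FALSE)
}

mk_pairs <- function(n, prefix = "P") {
  pid <- sprintf("%s%04d", prefix, seq_len(n))
  data.frame(pair_id = pid,
             id1 = paste0(pid, "/1"), seq1 = strrep("A", 10),
             qual1 = strrep("I", 10),
             id2 = paste0(pid, "/2"), seq2 = strrep("C", 10),
             qual2 = strrep("I", 10), stringsAsFactors = FALSE)
}

# reverse-translate a protein deterministically (first codon per residue)
first_codon_cds <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(protein, "")[[1L]],
               function(a) names(gc)[gc == a][1L], character(1L)),
        collapse = "")
}
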