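# Independent reference implementations used as oracles. These share no
# code with the package: plain-R dynamic programming and direct
# recomputation from alignment strings.

# Smith-Waterman maximum local score, Gotoh affine gaps: a gap run of
# length k costs gap_open + k * gap_extend. Scoring only, O(nm).
ref_sw_score <- function(a, b, mat, gap_open, gap_extend) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(0)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in x (consuming y)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in y (consuming x)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - gap_open - gap_extend,
                               E[i + 1L, j] - gap_extend)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - gap_open - gap_extend,
                               F[i, j + 1L] - gap_extend)
      H[i + 1L, j + 1L] <- max(0,
                               H[i, j] + mat[x[i], y[j]],
                               E[i + 1L, j + 1L],
                               F[i + 1L, j + 1L])
    }
  }
  max(H)
}

# six-frame translated best local score: enumerate frames by hand,
# split at stops, align each stop-free segment
ref_translated_score <- function(seq, subject, mat, gap_open, gap_extend) {
  best <- 0
  for (strand_seq in c(seq, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))))) {
    for (off in 0:2) {
      s <- substr(strand_seq, off + 1L, nchar(strand_seq))
      nc <- nchar(s) %/% 3L
      if (nc < 1L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, 1L, 3L * nc)),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      for (seg in strsplit(aa, "*", fixed = TRUE)[[1L]]) {
        if (!nzchar(seg)) next
        best <- max(best, ref_sw_score(seg, subject, mat, gap_open,
                                       gap_extend))
      }
    }
  }
  best
}

# score and column counts recomputed directly from the two aligned rows
ref_alignment_score <- function(aq, as_, mat, gap_open, gap_extend) {
  x <- strsplit(aq, "", fixed = TRUE)[[1L]]
  y <- strsplit(as_, "", fixed = TRUE)[[1L]]
  sc <- 0
  for (k in seq_along(x)) {
    if (x[k] != "-" && y[k] != "-") sc <- sc + mat[x[k], y[k]]
  }
  for (v in list(x, y)) {
    r <- rle(v == "-")
    runs <- r$lengths[r$values]
    if (length(runs)) sc <- sc - sum(gap_open + runs * gap_extend)
  }
  sc
}

ref_alignment_counts <- function(aq, as_, mat, never_match = character()) {
  x <- strsplit(aq, "", fixed = TRUE)[[1L]]
  y <- strsplit(as_, "", fixed = TRUE)[[1L]]
  ident <- 0L; pos <- 0L; gap_chars <- 0L
  for (k in seq_along(x)) {
    if (x[k] == "-" || y[k] == "-") {
      gap_chars <- gap_chars + 1L
    } else {
      if (x[k] == y[k] && !(x[k] %in% never_match)) ident <- ident + 1L
      if (mat[x[k], y[k]] > 0) pos <- pos + 1L
    }
  }
  opens <- sum(rle(x == "-")$values) + sum(rle(y == "-")$values)
  list(n_identical = ident, n_positive = pos, n_gap_chars = gap_chars,
       n_gap_opens = opens, alignment_length = length(x))
}

# exhaustive-candidate N50: the largest contig length L such that
# contigs of length >= L hold at least half the total bases
ref_n50 <- function(lengths) {
  total <- sum(lengths)
  feasible <- Filter(function(L) sum(lengths[lengths >= L]) >= total / 2,
                     unique(lengths))
  max(unlist(feasible))
}

ref_nt_matrix <- function(match = 2, mismatch = -3) {
  al <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(al, al))
  for (s in c("A", "C", "G", "T")) m[s, s] <- match
  m
}

ref_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
               replace = TRUE), collapse = "")
}
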