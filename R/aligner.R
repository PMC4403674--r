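# Local alignment engines standing in for BLASTn/BLASTx/BLASTp.
#
# All three engines are exact Smith-Waterman with affine gaps (a gap run
# of length k costs gap_open + k * gap_extend), computed by
# Biostrings::pairwiseAlignment. They return a common "alignment hit"
# row so downstream stages are agnostic to whether hits were computed
# in-process or parsed from an external BLAST tabular file. E-values are
# not computed in-process; ranking is by raw score with deterministic
# tie-breaking (higher identical count, then lexicographically smallest
# subject id).

BLAST12_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Default alignment scoring parameters
#'
#' Nucleotide: match +2, mismatch -3, gap open 5, gap extend 2.
#' Protein: BLOSUM62, gap open 11, gap extend 1. These are the classic
#' BLAST defaults; a gap run of length k costs open + k * extend.
#'
#' @return Named list with `nt` and `aa` scoring lists.
#' @export
default_scoring <- function() {
  list(nt = list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2),
       aa = list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1))
}

.nt_matrix <- function(match = 2, mismatch = -3) {
  al <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(al, al))
  diag(m) <- match
  # N is never a match, not even against itself
  m["N", "N"] <- mismatch
  m
}

.aa_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

.as_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(id = x$id[1L], seq = x$seq[1L])
  } else {
    stopifnot(is.list(x), !is.null(x$id), !is.null(x$seq))
    list(id = x$id, seq = x$seq)
  }
}

# column-wise metrics of one gapped alignment; `never_match` symbols
# (e.g. N) are excluded from the identity count even when equal
.alignment_metrics <- function(aq, as_, mat, never_match = character()) {
  a <- strsplit(aq, "", fixed = TRUE)[[1L]]
  b <- strsplit(as_, "", fixed = TRUE)[[1L]]
  stopifnot(length(a) == length(b))
  gap_a <- a == "-"
  gap_b <- b == "-"
  both <- !gap_a & !gap_b
  ident <- both & a == b & !(a %in% never_match)
  pos <- both
  if (any(both)) {
    pos[both] <- mat[cbind(a[both], b[both])] > 0
  }
  runs_a <- rle(gap_a)
  runs_b <- rle(gap_b)
  list(alignment_length = length(a),
       n_identical = sum(ident),
       n_mismatch = sum(both & !(a == b & !(a %in% never_match))),
       n_positive = sum(pos),
       n_gap_chars = sum(gap_a) + sum(gap_b),
       n_gap_opens = sum(runs_a$values) + sum(runs_b$values))
}

.hit_row <- function(query_id, subject_id, metrics, q_start, q_end,
                     s_start, s_end, frame, score, evalue = NA_real_,
                     aligned_query = NA_character_,
                     aligned_subject = NA_character_) {
  data.frame(query_id = query_id,
             subject_id = subject_id,
             pct_identity = 100 * metrics$n_identical / metrics$alignment_length,
             alignment_length = metrics$alignment_length,
             n_identical = metrics$n_identical,
             n_mismatch = metrics$n_mismatch,
             n_positive = metrics$n_positive,
             n_gap_chars = metrics$n_gap_chars,
             n_gap_opens = metrics$n_gap_opens,
             q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end,
             frame = frame, score = score, evalue = evalue,
             aligned_query = aligned_query,
             aligned_subject = aligned_subject,
             stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  .hit_row("", "", list(alignment_length = 0L, n_identical = 0L,
                        n_mismatch = 0L, n_positive = 0L,
                        n_gap_chars = 0L, n_gap_opens = 0L),
           0L, 0L, 0L, 0L, 0L, 0)[0L, ]
}

# one full local alignment pattern-vs-subject; returns NULL for an
# empty (score <= 0) alignment
.full_local <- function(pseq, sseq, mat, go, ge, xstring) {
  pa <- Biostrings::pairwiseAlignment(
    xstring(pseq), xstring(sseq), type = "local",
    substitutionMatrix = mat, gapOpening = go, gapExtension = ge)
  aq <- as.character(Biostrings::alignedPattern(pa))
  if (!nzchar(aq)) return(NULL)
  list(score = Biostrings::score(pa),
       aligned_query = aq,
       aligned_subject = as.character(Biostrings::alignedSubject(pa)),
       q_start = Biostrings::start(Biostrings::pattern(pa)),
       q_end = Biostrings::end(Biostrings::pattern(pa)),
       s_start = Biostrings::start(Biostrings::subject(pa)),
       s_end = Biostrings::end(Biostrings::subject(pa)))
}

.local_scores <- function(pseqs, sseq, mat, go, ge, xstringset, xstring) {
  Biostrings::pairwiseAlignment(
    xstringset(pseqs), xstring(sseq), type = "local",
    substitutionMatrix = mat, gapOpening = go, gapExtension = ge,
    scoreOnly = TRUE)
}

#' Best local nucleotide alignment of one query against a subject set
#'
#' Exact Smith-Waterman over every subject; the best-scoring alignment is
#' returned, ties broken by higher identical-base count and then by
#' lexicographically smallest subject id.
#'
#' @param query a one-row record data.frame or `list(id=, seq=)`.
#' @param subjects record data.frame of nucleotide subjects.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param min_score hits scoring below this are discarded.
#' @return One-row hit data.frame, or `NULL` when there is no hit.
#' @export
align_local_nt <- function(query, subjects,
                           scoring = default_scoring()$nt,
                           min_score = 1) {
  q <- .as_record(query)
  if (is.null(subjects) || nrow(subjects) == 0L || !nzchar(q$seq)) return(NULL)
  mat <- .nt_matrix(scoring$match, scoring$mismatch)
  go <- abs(scoring$gap_open)
  ge <- abs(scoring$gap_extend)
  scores <- .local_scores(subjects$seq, q$seq, mat, go, ge,
                          Biostrings::DNAStringSet, Biostrings::DNAString)
  best <- max(scores)
  if (best < min_score) return(NULL)
  cand <- which(scores == best)
  rows <- lapply(cand, function(i) {
    fl <- .full_local(q$seq, subjects$seq[i], mat, go, ge,
                      Biostrings::DNAString)
    if (is.null(fl)) return(NULL)
    m <- .alignment_metrics(fl$aligned_query, fl$aligned_subject, mat,
                            never_match = "N")
    .hit_row(q$id, subjects$id[i], m, fl$q_start, fl$q_end,
             fl$s_start, fl$s_end, frame = 0L, score = fl$score,
             aligned_query = fl$aligned_query,
             aligned_subject = fl$aligned_subject)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(rows) || nrow(rows) == 0L) return(NULL)
  rows[order(-rows$n_identical, rows$subject_id), ][1L, , drop = FALSE]
}

# stop-free segments of all six frame translations
.frame_segments <- function(seq) {
  out <- list()
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- translate_frame(seq, f)
    if (!nzchar(aa)) next
    r <- gregexpr("[^*]+", aa)[[1L]]
    if (r[1L] == -1L) next
    for (k in seq_along(r)) {
      st <- r[k]
      len <- attr(r, "match.length")[k]
      out[[length(out) + 1L]] <- list(
        frame = f, aa_start = st,
        aa_seq = substr(aa, st, st + len - 1L))
    }
  }
  out
}

# map amino-acid coordinates within a frame translation to 1-based
# nucleotide coordinates on the input (forward) strand
.aa_to_nt <- function(frame, aa_from, aa_to, seq_len) {
  off <- abs(frame) - 1L
  nt_from <- off + 3L * (aa_from - 1L) + 1L
  nt_to <- off + 3L * aa_to
  if (frame > 0L) c(nt_from, nt_to) else
    c(seq_len - nt_from + 1L, seq_len - nt_to + 1L)
}

#' Best translated (nucleotide query vs protein subjects) alignment
#'
#' The query is translated in all six frames; each frame is split into
#' stop-free segments which are aligned independently against every
#' subject by protein Smith-Waterman (so a hit never spans an in-frame
#' stop). Query coordinates in the returned hit are 1-based nucleotide
#' positions on the input strand: `q_start < q_end` on + frames and
#' `q_start > q_end` on - frames, the BLASTX convention.
#'
#' @param query a one-row nucleotide record or `list(id=, seq=)`.
#' @param subjects protein record data.frame.
#' @param matrix scoring matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param min_score hits scoring below this are discarded.
#' @param min_segment_aa frame segments shorter than this are skipped.
#' @return One-row hit data.frame with `frame` set, or `NULL`.
#' @export
align_translated <- function(query, subjects, matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1,
                             min_score = 1, min_segment_aa = 1L) {
  q <- .as_record(query)
  if (is.null(subjects) || nrow(subjects) == 0L) return(NULL)
  if (nchar(q$seq) < 3L) return(NULL)
  mat <- .aa_matrix(matrix)
  segs <- .frame_segments(q$seq)
  segs <- segs[vapply(segs, function(s) nchar(s$aa_seq), integer(1L)) >=
                 min_segment_aa]
  if (length(segs) == 0L) return(NULL)
  seg_seqs <- vapply(segs, `[[`, character(1L), "aa_seq")
  # score every (segment, subject) pair, then realize only the best
  score_mat <- vapply(seq_len(nrow(subjects)), function(j) {
    .local_scores(seg_seqs, subjects$seq[j], mat, gap_open, gap_extend,
                  Biostrings::AAStringSet, Biostrings::AAString)
  }, numeric(length(segs)))
  score_mat <- matrix(score_mat, nrow = length(segs))
  best <- max(score_mat)
  if (best < min_score) return(NULL)
  idx <- which(score_mat == best, arr.ind = TRUE)
  L <- nchar(q$seq)
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    si <- idx[r, 1L]; j <- idx[r, 2L]
    seg <- segs[[si]]
    fl <- .full_local(seg$aa_seq, subjects$seq[j], mat, gap_open,
                      gap_extend, Biostrings::AAString)
    if (is.null(fl)) return(NULL)
    aa_from <- seg$aa_start + fl$q_start - 1L
    aa_to <- seg$aa_start + fl$q_end - 1L
    nt <- .aa_to_nt(seg$frame, aa_from, aa_to, L)
    m <- .alignment_metrics(fl$aligned_query, fl$aligned_subject, mat)
    .hit_row(q$id, subjects$id[j], m, nt[1L], nt[2L],
             fl$s_start, fl$s_end, frame = seg$frame, score = fl$score,
             aligned_query = fl$aligned_query,
             aligned_subject = fl$aligned_subject)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(rows) || nrow(rows) == 0L) return(NULL)
  rows[order(-rows$n_identical, rows$subject_id), ][1L, , drop = FALSE]
}

#' Protein-protein local alignment against a subject set
#'
#' Smith-Waterman of the query against every subject; hits are sorted by
#' descending score (ties: higher identical count, then subject id) and
#' truncated to `max_targets`, mirroring BLASTp with `max_target_seqs`.
#' Percent similarity is available as `100 * n_positive /
#' alignment_length` (columns with a positive matrix score).
#'
#' @param query one-row protein record or `list(id=, seq=)`.
#' @param subjects protein record data.frame.
#' @param matrix scoring matrix name or matrix.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param max_targets maximum number of subjects reported.
#' @param min_score hits scoring below this are discarded.
#' @return Hit data.frame with up to `max_targets` rows (possibly empty).
#' @export
align_protein <- function(query, subjects, matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          max_targets = 1L, min_score = 1) {
  q <- .as_record(query)
  if (is.null(subjects) || nrow(subjects) == 0L || !nzchar(q$seq)) {
    return(.empty_hits())
  }
  mat <- .aa_matrix(matrix)
  scores <- .local_scores(subjects$seq, q$seq, mat, gap_open, gap_extend,
                          Biostrings::AAStringSet, Biostrings::AAString)
  keep <- which(scores >= min_score)
  if (length(keep) == 0L) return(.empty_hits())
  # realize alignments only for subjects that can make the cut
  ord <- keep[order(-scores[keep])]
  cutoff <- if (length(ord) > max_targets) {
    # include all subjects tied with the max_targets-th score
    sc <- scores[ord]
    ord[sc >= sc[max_targets]]
  } else ord
  rows <- lapply(cutoff, function(i) {
    fl <- .full_local(q$seq, subjects$seq[i], mat, gap_open, gap_extend,
                      Biostrings::AAString)
    if (is.null(fl)) return(NULL)
    m <- .alignment_metrics(fl$aligned_query, fl$aligned_subject, mat)
    .hit_row(q$id, subjects$id[i], m, fl$q_start, fl$q_end,
             fl$s_start, fl$s_end, frame = 0L, score = fl$score,
             aligned_query = fl$aligned_query,
             aligned_subject = fl$aligned_subject)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(rows) || nrow(rows) == 0L) return(.empty_hits())
  rows <- rows[order(-rows$score, -rows$n_identical, rows$subject_id), ]
  utils::head(rows, max_targets)
}

#' Parse a BLAST tabular (outfmt 6) file into hit rows
#'
#' Expects the 12-column default dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), optionally
#' extended with `positive` and `gaps` columns declared in a comment line
#' beginning `#columns:`. The identical-residue count is reconstructed as
#' `round(pident * length / 100)`. In translated mode the frame sign is
#' inferred from query coordinate orientation (`qstart > qend` means a
#' minus frame); the within-strand frame offset is not recoverable from
#' tabular output and is reported as +/-1.
#'
#' @param path file path.
#' @param mode one of `"nt"`, `"translated"`, `"protein"`.
#' @return Hit data.frame, one row per input row.
#' @export
parse_blast_tabular <- function(path, mode = c("nt", "translated", "protein")) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  cols <- BLAST12_COLS
  hdr <- grep("^#columns:", lines, value = TRUE)
  if (length(hdr) > 0L) {
    declared <- strsplit(trimws(sub("^#columns:", "", hdr[1L])),
                         "[ \t]+")[[1L]]
    if (!identical(declared[seq_len(12L)], BLAST12_COLS) ||
        !all(declared[-seq_len(12L)] %in% c("positive", "gaps"))) {
      stop("unsupported #columns: declaration in ", path)
    }
    cols <- declared
  }
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- lapply(keep, function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(cols)) {
      stop("line ", ln, " of ", path, ": expected ", length(cols),
           " tab-separated fields, found ", length(f))
    }
    names(f) <- cols
    num <- suppressWarnings(as.numeric(f[-c(1L, 2L)]))
    if (any(is.na(num))) {
      stop("line ", ln, " of ", path, ": non-numeric field '",
           f[-c(1L, 2L)][which(is.na(num))[1L]], "'")
    }
    v <- as.list(num)
    names(v) <- cols[-c(1L, 2L)]
    qs <- as.integer(v$qstart); qe <- as.integer(v$qend)
    frame <- if (mode == "translated") (if (qs > qe) -1L else 1L) else 0L
    len <- as.integer(v$length)
    n_ident <- as.integer(round(v$pident * len / 100))
    gap_chars <- if ("gaps" %in% cols) as.integer(v$gaps) else NA_integer_
    m <- list(alignment_length = len,
              n_identical = n_ident,
              n_mismatch = as.integer(v$mismatch),
              n_positive = if ("positive" %in% cols)
                as.integer(v$positive) else NA_integer_,
              n_gap_chars = gap_chars,
              n_gap_opens = as.integer(v$gapopen))
    h <- .hit_row(f[["qseqid"]], f[["sseqid"]], m, qs, qe,
                  as.integer(v$sstart), as.integer(v$send),
                  frame, v$bitscore, evalue = v$evalue)
    h$pct_identity <- v$pident
    h
  })
  if (length(rows) == 0L) return(.empty_hits())
  do.call(rbind, rows)
}

#' Write hit rows as a BLAST tabular (outfmt 6) file
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @param extended also write `positive` and `gaps` columns, declared in
#'   a `#columns:` header line.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path, extended = FALSE) {
  ev <- ifelse(is.na(hits$evalue), 0, hits$evalue)
  core <- data.frame(hits$query_id, hits$subject_id,
                     sprintf("%.3f", hits$pct_identity),
                     hits$alignment_length, hits$n_mismatch,
                     hits$n_gap_opens, hits$q_start, hits$q_end,
                     hits$s_start, hits$s_end,
                     format(ev, scientific = TRUE, digits = 3),
                     hits$score)
  con <- file(path, "w")
  on.exit(close(con))
  if (extended) {
    core$positive <- hits$n_positive
    core$gaps <- hits$n_gap_chars
    writeLines(paste0("#columns: ", paste(c(BLAST12_COLS, "positive", "gaps"),
                                          collapse = " ")), con)
  }
  utils::write.table(core, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
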