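# Genomic-contamination filter for paired mRNA-seq reads.
#
# A read passes when its best alignment against a reference mRNA set has
# a reported length inside [min_len, max_len]; reads with no alignment
# are contamination candidates and are dropped by default. Removal is
# propagated to mates so the output stays properly paired.

#' Construct a read filter policy
#'
#' The defaults keep reads whose best reference-mRNA alignment length is
#' within the inclusive window \[100, 102\] — for 101-bp reads this
#' retains essentially full-length mRNA matches (one indel of slack) and
#' discards partial, genomic-looking alignments.
#'
#' @param min_len,max_len inclusive bounds on the best alignment length.
#' @param drop_unaligned drop reads that have no reported alignment.
#' @param mate_propagation when `TRUE` (default) a pair is removed as
#'   soon as either read fails; when `FALSE` a pair is removed only when
#'   both reads fail on their own account.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_len = 100L, max_len = 102L,
                          drop_unaligned = TRUE, mate_propagation = TRUE) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (is.na(min_len) || is.na(max_len) || min_len > max_len) {
    stop("invalid alignment-length window: min_len must be <= max_len")
  }
  structure(list(min_len = min_len, max_len = max_len,
                 drop_unaligned = isTRUE(drop_unaligned),
                 mate_propagation = isTRUE(mate_propagation)),
            class = "filter_policy")
}

#' Alignment length of a read's best hit
#'
#' Best = highest score, ties broken by higher identical count then
#' lexicographically smallest subject id (the aligner's convention).
#'
#' @param read read record (or a bare id string).
#' @param hits hit data.frame for this read; every row must carry the
#'   read's id as `query_id`.
#' @return The best hit's `alignment_length`, or `NULL` when there are
#'   no hits.
#' @export
best_alignment_length <- function(read, hits) {
  id <- if (is.character(read)) read else .as_record(read)$id
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  if (any(hits$query_id != id)) {
    stop("hit with foreign query_id (expected ", id, ", found ",
         hits$query_id[hits$query_id != id][1L], ")")
  }
  ord <- order(-hits$score, -hits$n_identical, hits$subject_id)
  hits$alignment_length[ord[1L]]
}

# best alignment length per read id, as a named vector (NA = unaligned)
.best_lengths <- function(ids, hits) {
  out <- rep(NA_integer_, length(ids))
  names(out) <- ids
  if (is.null(hits) || nrow(hits) == 0L) return(out)
  hits <- hits[hits$query_id %in% ids, , drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  ord <- order(hits$query_id, -hits$score, -hits$n_identical,
               hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$query_id)
  out[hits$query_id[first]] <- hits$alignment_length[first]
  out
}

#' Filter read pairs by best reference-alignment length
#'
#' A read fails individually iff it is unaligned (and the policy drops
#' unaligned reads) or its best alignment length falls outside the
#' policy window. A pair is kept iff both reads pass; a read removed
#' solely because of its mate is tallied under `n_removed_mate`.
#'
#' @param pairs pair data.frame as from [read_fastq_pairs()].
#' @param hits hit data.frame covering any subset of the reads (a read
#'   absent from `hits` counts as unaligned).
#' @param policy a [filter_policy()].
#' @return list with `kept` (pair data.frame, input order preserved) and
#'   `report` (a `filter_report` list).
#' @export
filter_pairs <- function(pairs, hits = NULL, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  ids <- c(pairs$id1, pairs$id2)
  if (anyDuplicated(ids)) {
    stop("duplicate read ids across pairs: ",
         paste(unique(ids[duplicated(ids)])[1L], collapse = ", "))
  }
  len1 <- .best_lengths(pairs$id1, hits)
  len2 <- .best_lengths(pairs$id2, hits)
  fails <- function(len) {
    ifelse(is.na(len), policy$drop_unaligned,
           len < policy$min_len | len > policy$max_len)
  }
  f1 <- fails(len1)
  f2 <- fails(len2)
  drop_pair <- if (policy$mate_propagation) f1 | f2 else f1 & f2
  kept <- pairs[!drop_pair, , drop = FALSE]
  # attribute each removed read: own failure (length vs unaligned) or mate
  own1 <- f1[drop_pair]; own2 <- f2[drop_pair]
  l1 <- len1[drop_pair]; l2 <- len2[drop_pair]
  n_unaligned <- sum(own1 & is.na(l1)) + sum(own2 & is.na(l2))
  n_length <- sum(own1 & !is.na(l1)) + sum(own2 & !is.na(l2))
  n_mate <- sum(!own1) + sum(!own2)
  report <- structure(list(
    n_pairs_in = nrow(pairs),
    n_pairs_kept = nrow(kept),
    n_removed_length = n_length,
    n_removed_unaligned = n_unaligned,
    n_removed_mate = n_mate), class = "filter_report")
  list(kept = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("pairs in: %d  kept: %d  removed reads: ",
                     "%d length, %d unaligned, %d mate\n"),
              x$n_pairs_in, x$n_pairs_kept, x$n_removed_length,
              x$n_removed_unaligned, x$n_removed_mate))
  invisible(x)
}

#' Write kept pairs as two FASTQ files
#'
#' @param kept pair data.frame (the `kept` element of [filter_pairs()]).
#' @param out_r1,out_r2 output FASTQ paths.
#' @return c(out_r1, out_r2), invisibly.
#' @export
write_filtered_fastq <- function(kept, out_r1, out_r2) {
  stopifnot(!is.null(kept))
  write_fastq_pairs(kept, out_r1, out_r2)
}

#' Serialize a filter report as a one-row TSV
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(as.data.frame(unclass(report)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align reads to a reference mRNA set and report hits
#'
#' For speed, constant-width reads are first matched exactly against
#' both strands of every reference sequence (an exact full-length match
#' is the overwhelmingly common case for genuine mRNA reads); reads
#' without an exact match fall back to Smith-Waterman via
#' [align_local_nt()] when `sw_fallback` is `TRUE`.
#'
#' @param reads record data.frame of reads (`id`, `seq`).
#' @param reference record data.frame of mRNA reference sequences.
#' @param scoring nucleotide scoring list (see [default_scoring()]).
#' @param min_score minimum Smith-Waterman score for a fallback hit.
#' @param sw_fallback run Smith-Waterman for reads with no exact match.
#' @return Hit data.frame (one best hit per aligned read).
#' @export
align_reads_to_reference <- function(reads, reference,
                                     scoring = default_scoring()$nt,
                                     min_score = 30, sw_fallback = TRUE) {
  if (nrow(reads) == 0L) return(.empty_hits())
  widths <- nchar(reads$seq)
  hits <- vector("list", nrow(reads))
  exact <- rep(FALSE, nrow(reads))
  if (length(unique(widths)) == 1L && !any(grepl("N", reads$seq))) {
    w <- widths[1L]
    pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$seq))
    pd_rev <- Biostrings::PDict(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reads$seq)))
    m <- list(alignment_length = w, n_identical = w, n_mismatch = 0L,
              n_positive = w, n_gap_chars = 0L, n_gap_opens = 0L)
    for (j in seq_len(nrow(reference))) {
      subj <- Biostrings::DNAString(reference$seq[j])
      for (pd in list(pd_fwd, pd_rev)) {
        mi <- Biostrings::matchPDict(pd, subj)
        cnt <- S4Vectors::elementNROWS(mi)
        for (i in which(cnt > 0 & !exact)) {
          s1 <- IRanges::start(mi[[i]])[1L]
          hits[[i]] <- .hit_row(reads$id[i], reference$id[j], m,
                                1L, w, s1, s1 + w - 1L, frame = 0L,
                                score = w * scoring$match)
          exact[i] <- TRUE
        }
      }
    }
  }
  todo <- which(!exact)
  if (sw_fallback && length(todo) > 0L) {
    for (i in todo) {
      h <- align_local_nt(list(id = reads$id[i], seq = reads$seq[i]),
                          reference, scoring = scoring,
                          min_score = min_score)
      rc <- align_local_nt(list(id = reads$id[i],
                                seq = revcomp(reads$seq[i])),
                           reference, scoring = scoring,
                           min_score = min_score)
      if (!is.null(rc) && (is.null(h) || rc$score > h$score)) h <- rc
      # assigning NULL into a list would delete the slot and shift
      # every later element; leave no-hit reads untouched instead
      if (!is.null(h)) hits[[i]] <- h
    }
  }
  hits <- hits[!vapply(hits, is.null, logical(1L))]
  if (length(hits) == 0L) return(.empty_hits())
  do.call(rbind, hits)
}
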