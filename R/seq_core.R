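# Sequence data model, translation, FASTA/FASTQ I/O and contig statistics.
#
# Sequence collections are plain data.frames with at least `id` and `seq`
# columns (plus optional `description`, `qual`, `gene_symbol`, `gene_id`),
# so every downstream table stays inspectable with ordinary R tools;
# Biostrings objects are used internally for the heavy lifting.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a sequence record collection
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of sequences (same length as `id`).
#' @param ... further per-record columns (e.g. `description`,
#'   `gene_symbol`, `qual`), each recycled to the number of records.
#' @return A data.frame with one row per record.
#' @export
seq_records <- function(id, seq, ...) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("`id` and `seq` must have the same length")
  }
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  extras <- list(...)
  df <- data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
  for (nm in names(extras)) df[[nm]] <- extras[[nm]]
  qual <- df[["qual"]]
  if (!is.null(qual) && any(!is.na(qual) & nchar(qual) != nchar(seq))) {
    stop("quality strings must match sequence lengths")
  }
  df
}

.check_nt <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("invalid nucleotide symbol in sequence: ",
         substr(seq[bad][1L], 1L, 30L))
  }
  invisible(seq)
}

#' Reverse complement of a nucleotide sequence
#'
#' N complements to N. The empty string maps to itself.
#'
#' @param seq character vector over the alphabet {A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  seq <- toupper(as.character(seq))
  .check_nt(seq)
  out <- character(length(seq))
  nz <- nzchar(seq)
  out[nz] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[nz])))
  out
}

#' Translate a nucleotide sequence in a given reading frame
#'
#' Frames +1, +2, +3 read the forward strand starting at offsets 0, 1, 2;
#' frames -1, -2, -3 read the reverse complement the same way. Stop codons
#' render as `*`; any codon containing `N` renders as `X`; a trailing
#' incomplete codon is ignored. The standard genetic code is used with no
#' special treatment of the initiator codon.
#'
#' @param seq a single nucleotide string.
#' @param frame one of +1, +2, +3, -1, -2, -3.
#' @return The protein string (possibly empty).
#' @export
translate_frame <- function(seq, frame = 1L) {
  stopifnot(length(seq) == 1L)
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)) {
    stop("unknown frame value: ", frame, " (must be in +/-1..3)")
  }
  seq <- toupper(as.character(seq))
  .check_nt(seq)
  if (frame < 0L) seq <- revcomp(seq)
  off <- abs(frame) - 1L
  n <- nchar(seq) - off
  if (n < 3L) return("")
  n_codon <- n %/% 3L
  sub <- substr(seq, off + 1L, off + 3L * n_codon)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

#' Read a FASTA file into a record data.frame
#'
#' The header line is split into `id` (first whitespace-delimited token)
#' and `description` (the remainder, possibly empty).
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `seq`, `description`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id)) {
    stop("duplicate ids in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq_records(id = id, seq = as.character(ss), description = desc)
}

#' Write a record data.frame as FASTA
#'
#' @param records data.frame with `id`, `seq` and optional `description`.
#' @param path output path.
#' @param width line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  hdr <- records$id
  if (!is.null(records$description)) {
    has <- !is.na(records$description) & nzchar(records$description)
    hdr[has] <- paste(records$id[has], records$description[has])
  }
  ss <- Biostrings::BStringSet(records$seq)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = max(1L, as.integer(width)))
  invisible(path)
}

.read_fastq <- function(path) {
  qs <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) stop("malformed FASTQ in ", path, ": ",
                               conditionMessage(e), call. = FALSE)),
    # Biostrings warns about dropping (empty) metadata columns when it
    # splices sequences and qualities together; nothing is lost
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(id = names(qs),
             seq = as.character(qs),
             qual = as.character(Biostrings::quality(qs)),
             stringsAsFactors = FALSE)
}

.mate_stem <- function(id) sub("[/ ._][12]$", "", id)

#' Read paired FASTQ files
#'
#' Records are paired positionally; mate ids may share a stem with a
#' trailing `/1`, `/2` style suffix. A count mismatch between the two
#' files is an error naming both counts.
#'
#' @param path_r1,path_r2 paths to the R1 and R2 FASTQ files.
#' @return data.frame with one row per pair: `pair_id`, `id1`, `seq1`,
#'   `qual1`, `id2`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- .read_fastq(path_r1)
  r2 <- .read_fastq(path_r2)
  if (nrow(r1) != nrow(r2)) {
    stop("paired FASTQ record counts differ: ", nrow(r1), " in ", path_r1,
         " vs ", nrow(r2), " in ", path_r2)
  }
  bad1 <- which(nchar(r1$qual) != nchar(r1$seq))
  bad2 <- which(nchar(r2$qual) != nchar(r2$seq))
  if (length(bad1)) stop("quality length mismatch at record ", bad1[1L],
                         " of ", path_r1)
  if (length(bad2)) stop("quality length mismatch at record ", bad2[1L],
                         " of ", path_r2)
  data.frame(pair_id = .mate_stem(r1$id),
             id1 = r1$id, seq1 = r1$seq, qual1 = r1$qual,
             id2 = r2$id, seq2 = r2$seq, qual2 = r2$qual,
             stringsAsFactors = FALSE)
}

#' Write read pairs as two FASTQ files
#'
#' @param pairs data.frame as returned by [read_fastq_pairs()].
#' @param path_r1,path_r2 output paths.
#' @return c(path_r1, path_r2), invisibly.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  .write_one <- function(ids, seqs, quals, path) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    if (length(seqs) == 0L) {
      # a valid, empty FASTQ
      con <- file(path, "w"); close(con)
      return(invisible(path))
    }
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
    invisible(path)
  }
  .write_one(pairs$id1, pairs$seq1, pairs$qual1, path_r1)
  .write_one(pairs$id2, pairs$seq2, pairs$qual2, path_r2)
  invisible(c(path_r1, path_r2))
}

#' Contig length statistics (N50, mean, total)
#'
#' N50 is the smallest contig length L such that contigs of length >= L
#' sum to at least half of the total assembled bases (descending
#' cumulative-sum convention).
#'
#' @param lengths integer vector of contig lengths (all >= 1).
#' @return list of class `contig_stats` with `n_contigs`, `n50`,
#'   `mean_length` (full precision), `total_length`.
#' @export
contig_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stop("contig statistics undefined for an empty set")
  if (any(is.na(lengths)) || any(lengths < 1)) {
    stop("all contig lengths must be >= 1")
  }
  srt <- sort(lengths, decreasing = TRUE)
  total <- sum(srt)
  csum <- cumsum(srt)
  n50 <- srt[which(csum >= total / 2)[1L]]
  structure(list(n_contigs = length(lengths),
                 n50 = n50,
                 mean_length = total / length(lengths),
                 total_length = total),
            class = "contig_stats")
}

#' @export
print.contig_stats <- function(x, ...) {
  cat(sprintf("contigs: %d  N50: %d  mean: %s  total: %d\n",
              x$n_contigs, as.integer(x$n50),
              format(round(x$mean_length), big.mark = ","),
              as.integer(x$total_length)))
  invisible(x)
}

#' Serialize contig statistics as a one-row TSV
#'
#' Mean length is reported rounded to the nearest integer, matching the
#' precision conventionally printed in assembly reports; full precision
#' is retained in the `contig_stats` object itself.
#'
#' @param stats a `contig_stats` object.
#' @param sample sample label for the row.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contig_stats <- function(stats, sample, path) {
  df <- data.frame(sample = sample,
                   n_contigs = stats$n_contigs,
                   n50 = stats$n50,
                   mean_length = round(stats$mean_length),
                   total_length = stats$total_length)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
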