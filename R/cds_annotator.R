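# Ortholog-guided full-length CDS annotation.
#
# The CDS range is seeded by the best translated-alignment hit and
# extended on the reading strand to the nearest in-frame ATG upstream
# and the first in-frame stop downstream; a candidate is accepted only
# when both codons exist and the derived protein matches its ortholog at
# >= min_identity percent identity with a length difference of at most
# max_length_diff residues (both thresholds inclusive).

REJECT_REASONS <- c("no_hit", "no_start", "no_stop", "internal_stop",
                    "identity_below", "length_diff_above")

.codon_at <- function(seq, pos) substr(seq, pos, pos + 2L)

#' Derive a candidate CDS from a translated-alignment hit
#'
#' Working on the hit's strand and frame, the aligned query range is
#' extended upstream codon-by-codon until an ATG is found (failing with
#' `no_start` if an in-frame stop or the sequence edge comes first) and
#' downstream until the first in-frame stop codon (failing with
#' `no_stop` at the 3' edge). If the aligned region itself translates
#' with a stop, the candidate is rejected as `internal_stop`. The CDS
#' excludes the stop codon; coordinates are reported 1-based inclusive
#' on the forward strand with a strand flag.
#'
#' @param transcript one-row record data.frame or `list(id=, seq=)`.
#' @param hit one-row translated-mode hit for this transcript.
#' @param extend extend the hit to ATG/stop (default). With
#'   `extend = FALSE` the hit range itself must begin at an ATG and be
#'   followed immediately by a stop codon.
#' @return list with `status = "candidate"` (fields `cds_start`,
#'   `cds_end`, `strand`, `frame`, `protein`, `stop_codon`) or
#'   `status = "rejected"` with a `reason`.
#' @export
derive_cds <- function(transcript, hit, extend = TRUE) {
  tr <- .as_record(transcript)
  stopifnot(nrow(hit) == 1L)
  if (hit$query_id != tr$id) {
    stop("hit query_id ", hit$query_id, " does not match transcript ", tr$id)
  }
  if (hit$frame == 0L) {
    stop("derive_cds requires a translated-mode hit (frame != 0)")
  }
  L <- nchar(tr$seq)
  minus <- hit$frame < 0L
  s <- if (minus) revcomp(tr$seq) else tr$seq
  # aligned range on the reading strand (q_start > q_end on minus frames)
  rs_start <- if (minus) L - hit$q_start + 1L else hit$q_start
  rs_end <- if (minus) L - hit$q_end + 1L else hit$q_end
  if ((rs_end - rs_start + 1L) %% 3L != 0L) {
    stop("aligned query range is not a whole number of codons")
  }
  aligned_aa <- translate_frame(substr(s, rs_start, rs_end), 1L)
  if (grepl("*", aligned_aa, fixed = TRUE)) {
    return(list(status = "rejected", reason = "internal_stop"))
  }
  reject <- function(reason) list(status = "rejected", reason = reason)

  if (extend) {
    pos <- rs_start
    start_pos <- NA_integer_
    while (pos >= 1L) {
      cod <- .codon_at(s, pos)
      if (cod == "ATG") { start_pos <- pos; break }
      if (cod %in% STOP_CODONS) break
      pos <- pos - 3L
    }
    if (is.na(start_pos)) return(reject("no_start"))
    pos <- rs_end + 1L
    stop_pos <- NA_integer_
    while (pos + 2L <= L) {
      cod <- .codon_at(s, pos)
      if (cod %in% STOP_CODONS) { stop_pos <- pos; break }
      pos <- pos + 3L
    }
    if (is.na(stop_pos)) return(reject("no_stop"))
  } else {
    if (.codon_at(s, rs_start) != "ATG") return(reject("no_start"))
    stop_pos <- rs_end + 1L
    if (stop_pos + 2L > L || !.codon_at(s, stop_pos) %in% STOP_CODONS) {
      return(reject("no_stop"))
    }
    start_pos <- rs_start
  }
  cds_r1 <- start_pos
  cds_r2 <- stop_pos - 1L
  protein <- translate_frame(substr(s, cds_r1, cds_r2), 1L)
  if (grepl("*", protein, fixed = TRUE)) return(reject("internal_stop"))
  list(status = "candidate",
       cds_start = if (minus) L - cds_r2 + 1L else cds_r1,
       cds_end = if (minus) L - cds_r1 + 1L else cds_r2,
       strand = if (minus) "-" else "+",
       frame = hit$frame,
       protein = protein,
       stop_codon = .codon_at(s, stop_pos))
}

.annotation_row <- function(transcript_id, status, reject_reason = NA,
                            cds_start = NA, cds_end = NA, strand = NA,
                            frame = NA, protein = NA, ortholog_id = NA,
                            gene_symbol = NA, pct_identity = NA,
                            length_diff = NA) {
  data.frame(transcript_id = transcript_id, status = status,
             reject_reason = as.character(reject_reason),
             cds_start = as.integer(cds_start),
             cds_end = as.integer(cds_end),
             strand = as.character(strand), frame = as.integer(frame),
             protein = as.character(protein),
             ortholog_id = as.character(ortholog_id),
             gene_symbol = as.character(gene_symbol),
             pct_identity = as.numeric(pct_identity),
             length_diff = as.integer(length_diff),
             stringsAsFactors = FALSE)
}

#' Validate a CDS candidate against its ortholog
#'
#' Acceptance requires a structurally valid candidate (both start and
#' stop codons found) whose derived protein aligns to the ortholog with
#' percent identity >= `min_identity` (computed from a protein-protein
#' local alignment as `100 * n_identical / alignment_length`) and whose
#' length differs from the ortholog by at most `max_length_diff`
#' residues. Thresholds are inclusive. Rejection reasons are assigned in
#' fixed order: structural first, then `identity_below`, then
#' `length_diff_above`.
#'
#' @param candidate result of [derive_cds()] (or a `no_hit` rejection).
#' @param transcript_id transcript identifier for the annotation row.
#' @param ortholog one-row ortholog protein record (needs `id`, `seq`,
#'   and optionally `gene_symbol`).
#' @param min_identity minimum percent identity (default 85).
#' @param max_length_diff maximum protein length difference (default 10).
#' @param matrix,gap_open,gap_extend protein alignment scoring.
#' @return One-row annotation data.frame.
#' @export
validate_annotation <- function(candidate, transcript_id, ortholog,
                                min_identity = 85, max_length_diff = 10,
                                matrix = "BLOSUM62", gap_open = 11,
                                gap_extend = 1) {
  if (min_identity < 0 || max_length_diff < 0) {
    stop("thresholds must be non-negative")
  }
  if (!identical(candidate$status, "candidate")) {
    return(.annotation_row(transcript_id, "rejected",
                           reject_reason = candidate$reason))
  }
  ort <- if (is.data.frame(ortholog)) ortholog else as.data.frame(ortholog)
  gene_symbol <- if (!is.null(ort$gene_symbol)) ort$gene_symbol[1L] else NA
  hits <- align_protein(list(id = "derived", seq = candidate$protein),
                        ort[, c("id", "seq")], matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend,
                        max_targets = 1L, min_score = 1)
  pct <- if (nrow(hits) == 0L) 0 else hits$pct_identity[1L]
  ldiff <- abs(nchar(candidate$protein) - nchar(ort$seq[1L]))
  if (pct < min_identity) {
    return(.annotation_row(transcript_id, "rejected", "identity_below",
                           candidate$cds_start, candidate$cds_end,
                           candidate$strand, candidate$frame,
                           candidate$protein, ort$id[1L], gene_symbol,
                           pct, ldiff))
  }
  if (ldiff > max_length_diff) {
    return(.annotation_row(transcript_id, "rejected", "length_diff_above",
                           candidate$cds_start, candidate$cds_end,
                           candidate$strand, candidate$frame,
                           candidate$protein, ort$id[1L], gene_symbol,
                           pct, ldiff))
  }
  .annotation_row(transcript_id, "accepted", NA,
                  candidate$cds_start, candidate$cds_end,
                  candidate$strand, candidate$frame, candidate$protein,
                  ort$id[1L], gene_symbol, pct, ldiff)
}

#' Annotate transcripts with full-length CDS guided by ortholog proteins
#'
#' Each transcript is matched to its single best ortholog (via
#' [align_translated()] in-process, or precomputed hits), the CDS is
#' derived and validated, and per-reason rejection tallies plus unique
#' protein/gene counts are summarized.
#'
#' @param transcripts record data.frame of transcript contigs.
#' @param orthologs protein record data.frame with a `gene_symbol`
#'   column.
#' @param hits optional precomputed translated-mode hit data.frame (e.g.
#'   from [parse_blast_tabular()]); when `NULL` the built-in aligner is
#'   used.
#' @param min_identity,max_length_diff acceptance thresholds.
#' @param min_hit_score minimum translated-alignment score for a hit to
#'   count (built-in aligner only).
#' @param matrix,gap_open,gap_extend protein alignment scoring.
#' @param extend passed to [derive_cds()].
#' @return list with `annotations` (one row per transcript) and
#'   `summary` (an `annotation_summary` list).
#' @export
annotate_transcripts <- function(transcripts, orthologs, hits = NULL,
                                 min_identity = 85, max_length_diff = 10,
                                 min_hit_score = 50, matrix = "BLOSUM62",
                                 gap_open = 11, gap_extend = 1,
                                 extend = TRUE) {
  if (is.null(orthologs$gene_symbol)) {
    stop("orthologs must carry a gene_symbol column")
  }
  rows <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    tr <- list(id = transcripts$id[i], seq = transcripts$seq[i])
    hit <- if (is.null(hits)) {
      align_translated(tr, orthologs, matrix = matrix,
                       gap_open = gap_open, gap_extend = gap_extend,
                       min_score = min_hit_score)
    } else {
      h <- hits[hits$query_id == tr$id, , drop = FALSE]
      if (nrow(h) == 0L) NULL else {
        h[order(-h$score, -h$n_identical, h$subject_id), ][1L, ,
                                                           drop = FALSE]
      }
    }
    if (is.null(hit)) {
      rows[[i]] <- .annotation_row(tr$id, "rejected", "no_hit")
      next
    }
    j <- match(hit$subject_id, orthologs$id)
    if (is.na(j)) {
      stop("hit subject ", hit$subject_id, " absent from ortholog set")
    }
    cand <- derive_cds(tr, hit, extend = extend)
    rows[[i]] <- validate_annotation(
      cand, tr$id, orthologs[j, , drop = FALSE],
      min_identity = min_identity, max_length_diff = max_length_diff,
      matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
  }
  annotations <- if (length(rows)) do.call(rbind, rows) else
    .annotation_row("", "")[0L, ]
  list(annotations = annotations,
       summary = annotation_summary(annotations))
}

#' Summarize an annotation table
#'
#' @param annotations annotation data.frame (one row per transcript).
#' @return `annotation_summary` list: `n_transcripts`, `n_annotated`,
#'   `n_unique_proteins` (distinct accepted protein strings),
#'   `n_unique_genes` (distinct accepted gene symbols, case-sensitive),
#'   `rejects_by_reason` named vector over all reject reasons.
#' @export
annotation_summary <- function(annotations) {
  acc <- annotations[!is.na(annotations$status) &
                       annotations$status == "accepted", , drop = FALSE]
  rej <- annotations$reject_reason[annotations$status == "rejected"]
  tab <- table(factor(rej, levels = REJECT_REASONS))
  structure(list(
    n_transcripts = nrow(annotations),
    n_annotated = nrow(acc),
    n_unique_proteins = length(unique(acc$protein)),
    n_unique_genes = length(unique(acc$gene_symbol[!is.na(acc$gene_symbol)])),
    rejects_by_reason = stats::setNames(as.integer(tab), names(tab))),
    class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("transcripts: %d  annotated: %d  unique proteins: %d  unique genes: %d\n",
              x$n_transcripts, x$n_annotated, x$n_unique_proteins,
              x$n_unique_genes))
  nz <- x$rejects_by_reason[x$rejects_by_reason > 0]
  if (length(nz)) {
    cat("rejected:", paste(names(nz), nz, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Write annotation outputs
#'
#' Writes (a) the accepted proteins as FASTA with ortholog id and gene
#' symbol in the header, (b) a CDS feature TSV (1-based inclusive
#' coordinates), (c) a rejects TSV with reasons, and (d) a one-row
#' summary TSV.
#'
#' @param result list from [annotate_transcripts()].
#' @param out_prefix path prefix for the output files.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_annotations <- function(result, out_prefix) {
  ann <- result$annotations
  acc <- ann[ann$status == "accepted", , drop = FALSE]
  rej <- ann[ann$status == "rejected", , drop = FALSE]
  paths <- c(proteins = paste0(out_prefix, "_proteins.fa"),
             cds = paste0(out_prefix, "_cds.tsv"),
             rejects = paste0(out_prefix, "_rejects.tsv"),
             summary = paste0(out_prefix, "_summary.tsv"))
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  write_fasta(seq_records(
    id = if (nrow(acc)) acc$transcript_id else character(),
    seq = if (nrow(acc)) acc$protein else character(),
    description = if (nrow(acc))
      paste0("ortholog=", acc$ortholog_id, " gene_symbol=",
             acc$gene_symbol) else character()), paths["proteins"])
  utils::write.table(
    acc[, c("transcript_id", "cds_start", "cds_end", "strand", "frame",
            "gene_symbol", "pct_identity", "length_diff")],
    paths["cds"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rej[, c("transcript_id", "reject_reason")],
                     paths["rejects"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- result$summary
  utils::write.table(
    data.frame(n_transcripts = s$n_transcripts,
               n_annotated = s$n_annotated,
               n_unique_proteins = s$n_unique_proteins,
               n_unique_genes = s$n_unique_genes,
               t(s$rejects_by_reason)),
    paths["summary"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
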