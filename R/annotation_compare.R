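# Quantitative comparison of two protein annotation sets against a
# common reference proteome: per-protein best-hit metrics (percent
# identity, percent similarity, gaps), set-level means, gene-symbol
# presence filtering, single-isoform overlap, and asymmetric
# missing-gene detection.

#' Read a protein set (FASTA plus optional metadata TSV)
#'
#' The metadata TSV emulates a BioMart-style export with columns
#' `protein_id`, `gene_id`, `gene_symbol`, `description`; rows are
#' joined to the FASTA records by `protein_id`.
#'
#' @param fasta_path protein FASTA path.
#' @param meta_path optional metadata TSV path.
#' @return data.frame with columns `protein_id`, `gene_id`,
#'   `gene_symbol`, `description`, `seq`.
#' @export
read_protein_set <- function(fasta_path, meta_path = NULL) {
  fa <- read_fasta(fasta_path)
  set <- data.frame(protein_id = fa$id, gene_id = NA_character_,
                    gene_symbol = NA_character_,
                    description = fa$description, seq = fa$seq,
                    stringsAsFactors = FALSE)
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                              colClasses = "character")
    j <- match(set$protein_id, meta$protein_id)
    for (col in c("gene_id", "gene_symbol", "description")) {
      if (!is.null(meta[[col]])) {
        set[[col]] <- ifelse(is.na(j), set[[col]], meta[[col]][j])
      }
    }
  }
  if (any(!nzchar(set$seq))) stop("protein set contains an empty sequence")
  set
}

#' Compare a protein set to a reference proteome by best-hit alignment
#'
#' Each protein is aligned against the reference (best hit only,
#' mirroring BLASTp with `max_target_seqs = 1`); percent identity,
#' percent similarity (positive-scoring columns) and gap counts are
#' taken from that alignment. Proteins with no hit count toward
#' `n_proteins` but are excluded from the means.
#'
#' @param set protein set data.frame (see [read_protein_set()]).
#' @param reference record data.frame of reference proteins.
#' @param hits optional precomputed protein-mode hit data.frame with
#'   `n_positive`/`n_gap_chars` populated; when `NULL` the built-in
#'   aligner is used.
#' @param max_targets best hits per protein retained before taking the
#'   top one (kept for parity with the BLAST option; only the top hit
#'   enters the summary).
#' @param min_score minimum alignment score for a hit to count.
#' @param matrix,gap_open,gap_extend protein alignment scoring.
#' @return `comparison_summary` list: `n_proteins`, `n_with_hit`,
#'   `mean_pct_identity`, `mean_pct_similarity`, `mean_gaps`, and
#'   `per_protein` data.frame.
#' @export
compare_to_reference <- function(set, reference, hits = NULL,
                                 max_targets = 1L, min_score = 30,
                                 matrix = "BLOSUM62", gap_open = 11,
                                 gap_extend = 1) {
  if (is.null(set) || nrow(set) == 0L) stop("empty protein set")
  rows <- vector("list", nrow(set))
  for (i in seq_len(nrow(set))) {
    h <- if (is.null(hits)) {
      align_protein(list(id = set$protein_id[i], seq = set$seq[i]),
                    reference, matrix = matrix, gap_open = gap_open,
                    gap_extend = gap_extend, max_targets = max_targets,
                    min_score = min_score)
    } else {
      hh <- hits[hits$query_id == set$protein_id[i], , drop = FALSE]
      hh[order(-hh$score, -hh$n_identical, hh$subject_id), ]
    }
    if (nrow(h) == 0L) next
    h <- h[1L, ]
    if (is.na(h$n_positive) || is.na(h$n_gap_chars)) {
      stop("hit for ", set$protein_id[i],
           " lacks positive/gap counts; supply extended tabular input ",
           "or use the built-in aligner")
    }
    rows[[i]] <- data.frame(
      protein_id = set$protein_id[i],
      gene_symbol = if (is.null(set$gene_symbol)) NA_character_ else
        set$gene_symbol[i],
      subject_id = h$subject_id,
      pct_identity = h$pct_identity,
      pct_similarity = 100 * h$n_positive / h$alignment_length,
      gaps = h$n_gap_chars,
      gap_opens = h$n_gap_opens,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(per)) {
    per <- data.frame(protein_id = character(), gene_symbol = character(),
                      subject_id = character(), pct_identity = numeric(),
                      pct_similarity = numeric(), gaps = integer(),
                      gap_opens = integer(), stringsAsFactors = FALSE)
  }
  .comparison_summary(nrow(set), per)
}

.comparison_summary <- function(n_proteins, per) {
  structure(list(
    n_proteins = n_proteins,
    n_with_hit = nrow(per),
    mean_pct_identity = if (nrow(per)) mean(per$pct_identity) else NA_real_,
    mean_pct_similarity = if (nrow(per)) mean(per$pct_similarity) else NA_real_,
    mean_gaps = if (nrow(per)) mean(per$gaps) else NA_real_,
    per_protein = per), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf(paste0("proteins: %d  with hit: %d  mean %%identity: %.2f  ",
                     "mean %%similarity: %.2f  mean gaps: %.2f\n"),
              x$n_proteins, x$n_with_hit, x$mean_pct_identity,
              x$mean_pct_similarity, x$mean_gaps))
  invisible(x)
}

#' Drop protein-set entries without a gene symbol
#'
#' @param set protein set data.frame.
#' @return The subset with a present, non-empty `gene_symbol`, order
#'   preserved.
#' @export
filter_by_symbol <- function(set) {
  keep <- !is.na(set$gene_symbol) & nzchar(set$gene_symbol)
  set[keep, , drop = FALSE]
}

# one representative row per gene symbol: the best-identity row
.gene_representatives <- function(per) {
  per <- per[!is.na(per$gene_symbol) & nzchar(per$gene_symbol), ,
             drop = FALSE]
  per <- per[order(per$gene_symbol, -per$pct_identity, per$protein_id), ,
             drop = FALSE]
  per[!duplicated(per$gene_symbol), , drop = FALSE]
}

#' Restrict two comparison summaries to shared single-isoform genes
#'
#' The gene list is the intersection of the gene symbols present (with a
#' hit) in both summaries and the supplied single-isoform list. When a
#' set has several proteins for a gene, its best-identity row represents
#' the gene. Returns parallel summaries over the common gene list.
#'
#' @param summary_a,summary_b `comparison_summary` objects.
#' @param single_isoform_genes character vector of single-isoform gene
#'   symbols.
#' @return list with `genes` (sorted character vector) and `summary_a`,
#'   `summary_b` restricted to those genes.
#' @export
single_isoform_overlap <- function(summary_a, summary_b,
                                   single_isoform_genes) {
  rep_a <- .gene_representatives(summary_a$per_protein)
  rep_b <- .gene_representatives(summary_b$per_protein)
  genes <- sort(intersect(intersect(rep_a$gene_symbol, rep_b$gene_symbol),
                          single_isoform_genes))
  sub_a <- rep_a[rep_a$gene_symbol %in% genes, , drop = FALSE]
  sub_b <- rep_b[rep_b$gene_symbol %in% genes, , drop = FALSE]
  list(genes = genes,
       summary_a = .comparison_summary(length(genes), sub_a),
       summary_b = .comparison_summary(length(genes), sub_b))
}

#' Gene symbols present in one set but matched in the other
#'
#' @param symbols_a character vector of gene symbols in set A.
#' @param summary_b `comparison_summary` for set B.
#' @return Sorted, deduplicated symbols of A absent from B's with-hit
#'   rows.
#' @export
missing_genes <- function(symbols_a, summary_b) {
  a <- unique(symbols_a[!is.na(symbols_a) & nzchar(symbols_a)])
  b <- summary_b$per_protein$gene_symbol
  b <- b[!is.na(b)]
  sort(setdiff(a, b))
}

#' Write comparison outputs
#'
#' Writes the per-protein TSV and a one-row summary TSV (source label,
#' mean percent identity, mean percent similarity, mean gaps).
#'
#' @param summary a `comparison_summary`.
#' @param source_label label for the summary row.
#' @param out_prefix output path prefix.
#' @return Named vector of paths, invisibly.
#' @export
write_comparison <- function(summary, source_label, out_prefix) {
  paths <- c(per_protein = paste0(out_prefix, "_per_protein.tsv"),
             summary = paste0(out_prefix, "_summary.tsv"))
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(summary$per_protein, paths["per_protein"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(source = source_label,
               n_proteins = summary$n_proteins,
               n_with_hit = summary$n_with_hit,
               mean_pct_identity = summary$mean_pct_identity,
               mean_pct_similarity = summary$mean_pct_similarity,
               mean_gaps = summary$mean_gaps),
    paths["summary"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
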