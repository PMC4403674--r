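# End-to-end orchestration: simulate (or load) inputs, filter reads,
# compute contig statistics, annotate transcripts, compare annotation
# sets, and emit a deterministic run report. De novo assembly itself is
# delegated: the pipeline consumes contigs directly (for synthetic runs,
# the simulated transcripts stand in as contigs).

.config_defaults <- function() {
  list(seed = 1L,
       # synthetic-data generation (used when no input files are given)
       n_genes = 50L, n_transcripts = NULL,
       protein_len_range = c(100L, 500L),
       utr5_range = c(20L, 200L), utr3_range = c(50L, 300L),
       substitution_rate = 0, indel_rate = 0,
       frac_decoy = 0.2, frac_truncated = 0.1, frac_antisense = 0.5,
       read_length = 101L, fragment_len_mean = 300,
       fragment_len_sd = 30, coverage = 1,
       frac_contaminant_pairs = 0.1, frac_single_isoform = 0.5,
       frac_blank_symbol = 0.1, frac_deletion = 0.1,
       frac_elevated_sub = 0.1, degrade_substitution_rate = 0.05,
       deletion_len_range = c(3L, 10L),
       # optional input files (all simulated when NULL)
       transcripts_fa = NULL, orthologs_fa = NULL,
       reads_r1 = NULL, reads_r2 = NULL,
       setb_fa = NULL, setb_meta = NULL, single_isoform_list = NULL,
       # read filter policy
       min_len = 100L, max_len = 102L, drop_unaligned = TRUE,
       mate_propagation = TRUE, read_min_score = 30,
       # annotation thresholds
       min_identity = 85, max_length_diff = 10, min_hit_score = 50,
       extend_cds = TRUE,
       # comparison
       max_targets = 1L, compare_min_score = 30,
       # aligner scoring
       nt_match = 2, nt_mismatch = -3, nt_gap_open = 5, nt_gap_extend = 2,
       aa_matrix = "BLOSUM62", aa_gap_open = 11, aa_gap_extend = 1,
       # hit source: builtin aligner or external BLAST tabular files
       mode = "builtin",
       transcript_hits_tsv = NULL, read_hits_tsv = NULL,
       seta_hits_tsv = NULL, setb_hits_tsv = NULL)
}

#' Validate a pipeline configuration
#'
#' Reads a flat YAML key-value file (or an override list), applies
#' defaults, rejects unknown keys and checks ranges.
#'
#' @param path YAML config file path, or `NULL`.
#' @param overrides named list overriding file values (applied last).
#' @return A `pipeline_config` list.
#' @export
validate_config <- function(path = NULL, overrides = list()) {
  cfg <- .config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user[names(overrides)] <- overrides
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  int_keys <- c("seed", "n_genes", "min_len", "max_len", "read_length",
                "max_targets")
  for (k in int_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v)) {
      stop("config key '", k, "' must be a single integer")
    }
    cfg[[k]] <- as.integer(v)
  }
  if (cfg$min_len > cfg$max_len) {
    stop("config range violation: min_len (", cfg$min_len,
         ") exceeds max_len (", cfg$max_len, ")")
  }
  if (cfg$min_identity < 0 || cfg$min_identity > 100) {
    stop("config key 'min_identity' must lie in [0, 100]")
  }
  if (cfg$max_length_diff < 0) {
    stop("config key 'max_length_diff' must be >= 0")
  }
  if (!cfg$mode %in% c("builtin", "external_tabular")) {
    stop("config key 'mode' must be 'builtin' or 'external_tabular'")
  }
  for (k in c("transcripts_fa", "orthologs_fa", "reads_r1", "reads_r2",
              "setb_fa", "setb_meta", "single_isoform_list",
              "transcript_hits_tsv", "read_hits_tsv", "seta_hits_tsv",
              "setb_hits_tsv")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("config input path does not exist: ", k, " = ", cfg[[k]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

.sim_config_from <- function(cfg) {
  sim_config(seed = cfg$seed, n_genes = cfg$n_genes,
             n_transcripts = cfg$n_transcripts,
             protein_len_range = cfg$protein_len_range,
             utr5_range = cfg$utr5_range, utr3_range = cfg$utr3_range,
             substitution_rate = cfg$substitution_rate,
             indel_rate = cfg$indel_rate, frac_decoy = cfg$frac_decoy,
             frac_truncated = cfg$frac_truncated,
             frac_antisense = cfg$frac_antisense,
             read_length = cfg$read_length,
             fragment_len_mean = cfg$fragment_len_mean,
             fragment_len_sd = cfg$fragment_len_sd,
             coverage = cfg$coverage,
             frac_contaminant_pairs = cfg$frac_contaminant_pairs,
             frac_single_isoform = cfg$frac_single_isoform,
             frac_blank_symbol = cfg$frac_blank_symbol,
             frac_deletion = cfg$frac_deletion,
             frac_elevated_sub = cfg$frac_elevated_sub,
             degrade_substitution_rate = cfg$degrade_substitution_rate,
             deletion_len_range = cfg$deletion_len_range)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    cl <- conditionCall(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         if (!is.null(cl)) paste0(" [in ", deparse(cl)[1L], "]"),
         call. = FALSE)
  })
}

#' Score accepted annotations against a truth manifest
#'
#' A true positive is an accepted annotation of a full-length coding
#' transcript (origin `coding`, truncation `none`); any other accepted
#' annotation is a false positive; a full-length coding transcript with
#' no accepted annotation is a false negative. Coordinate exactness is
#' the fraction of true positives whose CDS range and strand equal the
#' truth.
#'
#' @param annotations annotation data.frame from
#'   [annotate_transcripts()].
#' @param manifest transcript truth manifest from
#'   [simulate_transcripts()].
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `coord_exact_frac`.
#' @export
score_annotations <- function(annotations, manifest) {
  m <- manifest[match(annotations$transcript_id, manifest$id), ]
  full <- m$origin == "coding" & m$truncation == "none"
  acc <- annotations$status == "accepted"
  tp <- sum(acc & full)
  fp <- sum(acc & !full)
  fn <- sum(!acc & full)
  exact <- acc & full &
    annotations$cds_start == m$true_cds_start &
    annotations$cds_end == m$true_cds_end &
    annotations$strand == m$strand
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       coord_exact_frac = if (tp > 0) sum(exact) / tp else NA_real_)
}

#' Run the full pipeline
#'
#' Stages: simulate or load inputs; filter read pairs against the
#' contig set by best-alignment length; compute contig statistics;
#' annotate transcripts with full-length CDS; compare the resulting
#' annotation set and the second (degraded/external) set against the
#' ortholog reference proteome. All intermediate files are written
#' under `out_dir`; the returned run report (also written as
#' `report.md` and TSVs) is byte-reproducible for a fixed config.
#'
#' @param config a `pipeline_config` from [validate_config()].
#' @param out_dir output directory.
#' @param quiet suppress per-stage log lines.
#' @return A `run_report` list.
#' @export
run_pipeline <- function(config, out_dir = tempfile("transannot_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message("[transannot] ", ...)

  # --- inputs -------------------------------------------------------
  inputs <- .stage("inputs", {
    if (is.null(config$transcripts_fa)) {
      log("simulating inputs (seed ", config$seed, ")")
      sim <- simulate_all(.sim_config_from(config))
      write_sim_outputs(sim, file.path(out_dir, "sim"))
      list(transcripts = sim$transcripts, orthologs = sim$proteome,
           reads = sim$reads, set_b = sim$set_b,
           single_isoform = sim$single_isoform,
           transcript_manifest = sim$transcript_manifest)
    } else {
      tr <- read_fasta(config$transcripts_fa)
      ort <- read_fasta(config$orthologs_fa)
      sym <- sub(".*gene_symbol=(\\S+).*", "\\1", ort$description)
      ort$gene_symbol <- ifelse(grepl("gene_symbol=", ort$description),
                                sym, NA_character_)
      reads <- if (!is.null(config$reads_r1)) {
        read_fastq_pairs(config$reads_r1, config$reads_r2)
      } else NULL
      set_b <- if (!is.null(config$setb_fa)) {
        read_protein_set(config$setb_fa, config$setb_meta)
      } else NULL
      si <- if (!is.null(config$single_isoform_list)) {
        readLines(config$single_isoform_list)
      } else character()
      list(transcripts = tr, orthologs = ort, reads = reads,
           set_b = set_b, single_isoform = si,
           transcript_manifest = NULL)
    }
  })

  # --- read filter --------------------------------------------------
  filter_report <- NULL
  if (!is.null(inputs$reads)) {
    filter_report <- .stage("read_filter", {
      log("filtering ", nrow(inputs$reads), " read pairs")
      reads <- seq_records(
        id = c(inputs$reads$id1, inputs$reads$id2),
        seq = c(inputs$reads$seq1, inputs$reads$seq2))
      hits <- if (!is.null(config$read_hits_tsv)) {
        parse_blast_tabular(config$read_hits_tsv, mode = "nt")
      } else {
        align_reads_to_reference(
          reads, inputs$transcripts,
          scoring = list(match = config$nt_match,
                         mismatch = config$nt_mismatch,
                         gap_open = config$nt_gap_open,
                         gap_extend = config$nt_gap_extend),
          min_score = config$read_min_score)
      }
      policy <- filter_policy(config$min_len, config$max_len,
                              config$drop_unaligned,
                              config$mate_propagation)
      res <- filter_pairs(inputs$reads, hits, policy)
      write_filtered_fastq(res$kept,
                           file.path(out_dir, "filtered_R1.fastq"),
                           file.path(out_dir, "filtered_R2.fastq"))
      write_filter_report(res$report,
                          file.path(out_dir, "filter_report.tsv"))
      res$report
    })
  }

  # --- contig statistics -------------------------------------------
  stats <- .stage("contig_stats", {
    s <- contig_stats(nchar(inputs$transcripts$seq))
    write_contig_stats(s, "contigs", file.path(out_dir, "contig_stats.tsv"))
    s
  })

  # --- annotation ---------------------------------------------------
  ann <- .stage("annotate", {
    log("annotating ", nrow(inputs$transcripts), " transcripts")
    hits <- if (!is.null(config$transcript_hits_tsv)) {
      parse_blast_tabular(config$transcript_hits_tsv, mode = "translated")
    } else NULL
    res <- annotate_transcripts(
      inputs$transcripts, inputs$orthologs, hits = hits,
      min_identity = config$min_identity,
      max_length_diff = config$max_length_diff,
      min_hit_score = config$min_hit_score, matrix = config$aa_matrix,
      gap_open = config$aa_gap_open, gap_extend = config$aa_gap_extend,
      extend = config$extend_cds)
    write_annotations(res, file.path(out_dir, "annotation"))
    res
  })

  # --- comparison ---------------------------------------------------
  comparison <- NULL
  if (!is.null(inputs$set_b)) {
    comparison <- .stage("compare", {
      acc <- ann$annotations[ann$annotations$status == "accepted", ,
                             drop = FALSE]
      set_a <- data.frame(protein_id = acc$transcript_id,
                          gene_id = NA_character_,
                          gene_symbol = acc$gene_symbol,
                          description = NA_character_,
                          seq = acc$protein, stringsAsFactors = FALSE)
      log("comparing ", nrow(set_a), " + ", nrow(inputs$set_b),
          " proteins against the reference proteome")
      aa_args <- list(matrix = config$aa_matrix,
                      gap_open = config$aa_gap_open,
                      gap_extend = config$aa_gap_extend,
                      max_targets = config$max_targets,
                      min_score = config$compare_min_score)
      cmp <- function(set, hits_path) {
        hits <- if (!is.null(hits_path)) {
          parse_blast_tabular(hits_path, mode = "protein")
        } else NULL
        do.call(compare_to_reference,
                c(list(set = set, reference = inputs$orthologs,
                       hits = hits), aa_args))
      }
      sum_a <- if (nrow(set_a) > 0L) cmp(set_a, config$seta_hits_tsv) else NULL
      sum_b <- cmp(inputs$set_b, config$setb_hits_tsv)
      set_b_sym <- filter_by_symbol(inputs$set_b)
      sum_b_sym <- if (nrow(set_b_sym) > 0L) {
        s <- cmp(set_b_sym, NULL)
        s
      } else NULL
      overlap <- if (!is.null(sum_a)) {
        single_isoform_overlap(sum_a, sum_b, inputs$single_isoform)
      } else NULL
      miss_in_b <- if (!is.null(sum_a)) {
        missing_genes(sum_a$per_protein$gene_symbol, sum_b)
      } else character()
      miss_in_a <- if (!is.null(sum_a)) {
        missing_genes(sum_b$per_protein$gene_symbol, sum_a)
      } else character()
      if (!is.null(sum_a)) {
        write_comparison(sum_a, "annotated_transcripts",
                         file.path(out_dir, "compare_setA"))
      }
      write_comparison(sum_b, "second_annotation_set",
                       file.path(out_dir, "compare_setB"))
      writeLines(miss_in_b, file.path(out_dir, "genes_missing_in_setB.txt"))
      writeLines(miss_in_a, file.path(out_dir, "genes_missing_in_setA.txt"))
      list(summary_a = sum_a, summary_b = sum_b,
           summary_b_symbol_filtered = sum_b_sym, overlap = overlap,
           genes_missing_in_b = miss_in_b,
           genes_missing_in_a = miss_in_a)
    })
  }

  truth_score <- if (!is.null(inputs$transcript_manifest)) {
    score_annotations(ann$annotations, inputs$transcript_manifest)
  } else NULL

  report <- structure(list(
    config = unclass(config), contig_stats = stats,
    filter_report = filter_report, annotation_summary = ann$summary,
    annotations = ann$annotations, comparison = comparison,
    truth_score = truth_score, out_dir = out_dir), class = "run_report")
  .write_report_md(report, file.path(out_dir, "report.md"))
  log("done; report at ", file.path(out_dir, "report.md"))
  report
}

.fmt <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

.write_report_md <- function(report, path) {
  s <- report$contig_stats
  lines <- c("# transannot run report", "",
             "## Contig statistics", "",
             "| sample | n_contigs | N50 | mean length | total length |",
             "|---|---|---|---|---|",
             sprintf("| contigs | %d | %d | %d | %d |", s$n_contigs,
                     as.integer(s$n50), as.integer(round(s$mean_length)),
                     as.integer(s$total_length)), "")
  if (!is.null(report$filter_report)) {
    f <- report$filter_report
    lines <- c(lines, "## Read filter", "",
               sprintf("- pairs in: %d; pairs kept: %d", f$n_pairs_in,
                       f$n_pairs_kept),
               sprintf("- reads removed: %d out-of-window, %d unaligned, %d via mate",
                       f$n_removed_length, f$n_removed_unaligned,
                       f$n_removed_mate), "")
  }
  a <- report$annotation_summary
  rej <- a$rejects_by_reason
  lines <- c(lines, "## Annotation", "",
             sprintf("- transcripts: %d; with full-length CDS: %d",
                     a$n_transcripts, a$n_annotated),
             sprintf("- unique proteins: %d; unique genes: %d",
                     a$n_unique_proteins, a$n_unique_genes),
             sprintf("- rejections: %s",
                     paste(names(rej), rej, sep = "=", collapse = ", ")), "")
  if (!is.null(report$truth_score)) {
    t <- report$truth_score
    lines <- c(lines, "## Truth scoring (synthetic run)", "",
               sprintf("- precision: %s; recall: %s; exact CDS coordinates: %s",
                       .fmt(t$precision, 4), .fmt(t$recall, 4),
                       .fmt(t$coord_exact_frac, 4)), "")
  }
  if (!is.null(report$comparison)) {
    cc <- report$comparison
    row <- function(label, x) {
      sprintf("| %s | %d | %s | %s | %s |", label, x$n_with_hit,
              .fmt(x$mean_pct_identity), .fmt(x$mean_pct_similarity),
              .fmt(x$mean_gaps))
    }
    lines <- c(lines, "## Comparison with the second annotation set", "",
               "| source | n with hit | mean % identity | mean % similarity | mean gaps |",
               "|---|---|---|---|---|")
    if (!is.null(cc$summary_a)) {
      lines <- c(lines, row("annotated transcripts", cc$summary_a))
    }
    lines <- c(lines, row("second set (all)", cc$summary_b))
    if (!is.null(cc$summary_b_symbol_filtered)) {
      lines <- c(lines, row("second set (with gene symbol)",
                            cc$summary_b_symbol_filtered))
    }
    if (!is.null(cc$overlap) && length(cc$overlap$genes) > 0L) {
      lines <- c(lines, "",
                 sprintf("Single-isoform overlap: %d genes.",
                         length(cc$overlap$genes)),
                 "",
                 "| source | mean % identity | mean % similarity | mean gaps |",
                 "|---|---|---|---|",
                 sprintf("| annotated transcripts | %s | %s | %s |",
                         .fmt(cc$overlap$summary_a$mean_pct_identity),
                         .fmt(cc$overlap$summary_a$mean_pct_similarity),
                         .fmt(cc$overlap$summary_a$mean_gaps)),
                 sprintf("| second set | %s | %s | %s |",
                         .fmt(cc$overlap$summary_b$mean_pct_identity),
                         .fmt(cc$overlap$summary_b$mean_pct_similarity),
                         .fmt(cc$overlap$summary_b$mean_gaps)))
    }
    lines <- c(lines, "",
               sprintf("Genes with no match in the second set: %d; genes of the second set with no match among annotated transcripts: %d.",
                       length(cc$genes_missing_in_b),
                       length(cc$genes_missing_in_a)), "")
  }
  lines <- c(lines, "## Configuration", "",
             sprintf("- seed: %d", report$config$seed),
             sprintf("- filter window: [%d, %d]; drop unaligned: %s",
                     report$config$min_len, report$config$max_len,
                     report$config$drop_unaligned),
             sprintf("- annotation thresholds: identity >= %s%%, length difference <= %d",
                     .fmt(report$config$min_identity, 1),
                     as.integer(report$config$max_length_diff)),
             sprintf("- hit source: %s", report$config$mode))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("transannot run report (", x$out_dir, ")\n", sep = "")
  print(x$contig_stats)
  if (!is.null(x$filter_report)) print(x$filter_report)
  print(x$annotation_summary)
  if (!is.null(x$comparison)) {
    if (!is.null(x$comparison$summary_a)) print(x$comparison$summary_a)
    print(x$comparison$summary_b)
  }
  invisible(x)
}
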