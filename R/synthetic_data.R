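# Fully-labeled synthetic inputs for every pipeline stage: an ortholog
# proteome, transcripts with known CDS (plus decoys, truncations and
# antisense orientation), error-free paired reads with genomic
# contaminants, and a degraded second annotation set. A ground-truth
# manifest accompanies each generator so precision/recall can be scored
# exactly. All generators are deterministic under the configured seed;
# each draws from its own named substream so adding one generator does
# not shift another's output.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codon lists per amino acid, from the standard genetic code
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

.sub_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483629
  for (c in utf8ToInt(name)) h <- (h * 131 + c) %% 2147483629
  as.integer(h + 1)
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale study: 50 ortholog genes with proteins
#' of 100-500 residues, one transcript per gene slot of which 20% are
#' non-coding decoys and 10% of the coding ones are truncated, half of
#' the coding transcripts emitted antisense (assemblers report arbitrary
#' strand), error-free 101-bp paired reads at 1x coverage with 10%
#' genomic contaminant pairs, and a second annotation set degraded with
#' 10% blank gene symbols, 10% internal deletions and 10% noisy entries.
#'
#' @param seed integer master seed.
#' @param n_genes number of ortholog genes.
#' @param n_transcripts total transcripts to emit (default `n_genes`).
#' @param protein_len_range ortholog protein length range (residues).
#' @param utr5_range,utr3_range UTR length ranges (nucleotides).
#' @param substitution_rate,indel_rate per-residue mutation
#'   probabilities applied to coding transcripts (amino-acid level,
#'   codon-aware: with `indel_rate = 0` the reading frame is preserved).
#' @param frac_decoy fraction of transcripts that are random non-coding
#'   decoys.
#' @param frac_truncated fraction of coding transcripts missing the
#'   start or the stop codon.
#' @param frac_antisense fraction of coding transcripts emitted as the
#'   reverse complement.
#' @param read_length read length in nucleotides.
#' @param fragment_len_mean,fragment_len_sd fragment length
#'   distribution (must satisfy `fragment_len_mean > read_length`).
#' @param coverage fold coverage for read simulation.
#' @param frac_contaminant_pairs fraction of read pairs drawn from an
#'   unrelated random genomic sequence.
#' @param frac_single_isoform fraction of genes flagged single-isoform.
#' @param frac_blank_symbol,frac_deletion,frac_elevated_sub degraded-set
#'   fractions: entries with a blank gene symbol, with an internal
#'   deletion, with elevated substitution noise.
#' @param degrade_substitution_rate per-residue substitution rate for
#'   noisy degraded entries.
#' @param deletion_len_range residue range of internal deletions in the
#'   degraded set.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 50L, n_transcripts = NULL,
                       protein_len_range = c(100L, 500L),
                       utr5_range = c(20L, 200L),
                       utr3_range = c(50L, 300L),
                       substitution_rate = 0, indel_rate = 0,
                       frac_decoy = 0.2, frac_truncated = 0.1,
                       frac_antisense = 0.5, read_length = 101L,
                       fragment_len_mean = 300, fragment_len_sd = 30,
                       coverage = 1, frac_contaminant_pairs = 0.1,
                       frac_single_isoform = 0.5,
                       frac_blank_symbol = 0.1, frac_deletion = 0.1,
                       frac_elevated_sub = 0.1,
                       degrade_substitution_rate = 0.05,
                       deletion_len_range = c(3L, 10L)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_transcripts = as.integer(
                if (is.null(n_transcripts)) n_genes else n_transcripts),
              protein_len_range = as.integer(protein_len_range),
              utr5_range = as.integer(utr5_range),
              utr3_range = as.integer(utr3_range),
              substitution_rate = substitution_rate,
              indel_rate = indel_rate, frac_decoy = frac_decoy,
              frac_truncated = frac_truncated,
              frac_antisense = frac_antisense,
              read_length = as.integer(read_length),
              fragment_len_mean = fragment_len_mean,
              fragment_len_sd = fragment_len_sd, coverage = coverage,
              frac_contaminant_pairs = frac_contaminant_pairs,
              frac_single_isoform = frac_single_isoform,
              frac_blank_symbol = frac_blank_symbol,
              frac_deletion = frac_deletion,
              frac_elevated_sub = frac_elevated_sub,
              degrade_substitution_rate = degrade_substitution_rate,
              deletion_len_range = as.integer(deletion_len_range))
  rates <- c(cfg$substitution_rate, cfg$indel_rate, cfg$frac_decoy,
             cfg$frac_truncated, cfg$frac_antisense,
             cfg$frac_contaminant_pairs, cfg$frac_single_isoform,
             cfg$frac_blank_symbol, cfg$frac_deletion,
             cfg$frac_elevated_sub, cfg$degrade_substitution_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates and fractions must lie in [0, 1]")
  }
  for (r in list(cfg$protein_len_range, cfg$utr5_range, cfg$utr3_range,
                 cfg$deletion_len_range)) {
    if (length(r) != 2L || any(r < 1L) || r[1L] > r[2L]) {
      stop("length ranges must be c(min, max) with 1 <= min <= max")
    }
  }
  if (cfg$n_genes < 1L || cfg$n_transcripts < 1L) {
    stop("n_genes and n_transcripts must be >= 1")
  }
  if (cfg$fragment_len_mean <= cfg$read_length) {
    stop("fragment_len_mean must exceed read_length")
  }
  structure(cfg, class = "sim_config")
}

.rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.reverse_translate <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) {
    cods <- .codons_by_aa[[a]]
    if (is.null(cods)) stop("cannot reverse-translate symbol ", a)
    cods[sample.int(length(cods), 1L)]
  }, character(1L)), collapse = "")
}

#' Simulate an ortholog reference proteome
#'
#' Proteins are random sequences over the 20 standard amino acids,
#' starting with M and free of internal stops; gene symbols are
#' `GENE0001`... A seeded subset of genes is flagged single-isoform.
#'
#' @param config a [sim_config()].
#' @return list with `proteins` (record data.frame with `gene_symbol`)
#'   and `single_isoform` (character vector of gene symbols).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config$seed, "proteome"))
  n <- config$n_genes
  lens <- sample(config$protein_len_range[1L]:config$protein_len_range[2L],
                 n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste0("M", paste(sample(AA20, L - 1L, replace = TRUE), collapse = ""))
  }, character(1L))
  symbols <- sprintf("GENE%04d", seq_len(n))
  proteins <- seq_records(id = sprintf("PROT%04d", seq_len(n)),
                          seq = seqs, gene_symbol = symbols,
                          description = paste0("gene_symbol=", symbols))
  n_si <- round(config$frac_single_isoform * n)
  single <- sort(sample(symbols, n_si))
  list(proteins = proteins, single_isoform = single)
}

.mutate_protein <- function(protein, sub_rate, indel_rate) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  n_sub <- 0L
  n_indel <- 0L
  if (sub_rate > 0 && length(aa) > 1L) {
    hit <- which(stats::runif(length(aa)) < sub_rate)
    hit <- hit[hit > 1L]  # the initiator M is never touched
    for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
    n_sub <- length(hit)
  }
  if (indel_rate > 0 && length(aa) > 1L) {
    hit <- which(stats::runif(length(aa)) < indel_rate)
    hit <- hit[hit > 1L]
    drop <- logical(length(aa))
    ins <- vector("list", length(aa))
    for (i in hit) {
      if (stats::runif(1L) < 0.5) drop[i] <- TRUE
      else ins[[i]] <- sample(AA20, 1L)
    }
    out <- character(0L)
    for (i in seq_along(aa)) {
      if (!drop[i]) out <- c(out, aa[i])
      if (!is.null(ins[[i]])) out <- c(out, ins[[i]])
    }
    aa <- out
    n_indel <- length(hit)
  }
  list(protein = paste(aa, collapse = ""), n_sub = n_sub,
       n_indel = n_indel)
}

#' Simulate transcripts with known CDS from an ortholog proteome
#'
#' Coding transcripts reverse-translate an (optionally mutated) ortholog
#' protein with uniform synonymous codon choice, wrap it in an ATG-led
#' CDS, a stop codon and random UTRs; a configured fraction are decoys
#' (random sequence), truncated (missing start or stop) or antisense.
#' The manifest records the origin, true CDS coordinates (forward
#' strand), strand, mutation counts and truncation label of every
#' transcript.
#'
#' @param proteome result of [simulate_proteome()].
#' @param config a [sim_config()].
#' @return list with `transcripts` (record data.frame) and `manifest`.
#' @export
simulate_transcripts <- function(proteome, config) {
  stopifnot(inherits(config, "sim_config"))
  prot <- proteome$proteins
  if (nrow(prot) == 0L) stop("empty proteome")
  set.seed(.sub_seed(config$seed, "transcripts"))
  n_tr <- config$n_transcripts
  n_decoy <- round(config$frac_decoy * n_tr)
  n_coding <- n_tr - n_decoy
  n_trunc <- round(config$frac_truncated * n_coding)
  trunc_idx <- if (n_trunc > 0L) sort(sample(n_coding, n_trunc)) else integer()
  trunc_kind <- rep(c("no_start", "no_stop"), length.out = n_trunc)
  n_anti <- round(config$frac_antisense * n_coding)
  anti_idx <- if (n_anti > 0L) sort(sample(n_coding, n_anti)) else integer()

  ids <- sprintf("TR%06d", seq_len(n_tr))
  seqs <- character(n_tr)
  man <- data.frame(id = ids, origin = "coding",
                    source_gene_symbol = NA_character_,
                    source_protein_id = NA_character_,
                    true_cds_start = NA_integer_,
                    true_cds_end = NA_integer_,
                    strand = NA_character_,
                    n_substitutions = 0L, n_indels = 0L,
                    truncation = "none", stringsAsFactors = FALSE)
  for (i in seq_len(n_coding)) {
    g <- ((i - 1L) %% nrow(prot)) + 1L
    mut <- .mutate_protein(prot$seq[g], config$substitution_rate,
                           config$indel_rate)
    p <- mut$protein
    trunc <- if (i %in% trunc_idx) trunc_kind[match(i, trunc_idx)] else "none"
    if (trunc == "no_start") {
      aa <- strsplit(p, "", fixed = TRUE)[[1L]]
      k <- 1L  # drop the initiator; keep dropping while the next is M
      while (k < length(aa) - 1L && aa[k + 1L] == "M") k <- k + 1L
      p_part <- paste(aa[(k + 1L):length(aa)], collapse = "")
      cds <- .reverse_translate(p_part)
      utr3 <- .rand_nt(sample(config$utr3_range[1L]:config$utr3_range[2L], 1L))
      seqs[i] <- paste0(cds, sample(STOP_CODONS, 1L), utr3)
      cds_start <- 1L
      cds_end <- nchar(cds)
    } else if (trunc == "no_stop") {
      d <- sample(1:3, 1L)  # also drop a few terminal codons
      p_part <- substr(p, 1L, nchar(p) - d)
      cds <- .reverse_translate(p_part)
      utr5 <- .rand_nt(sample(config$utr5_range[1L]:config$utr5_range[2L], 1L))
      seqs[i] <- paste0(utr5, cds)
      cds_start <- nchar(utr5) + 1L
      cds_end <- nchar(utr5) + nchar(cds)
    } else {
      cds <- .reverse_translate(p)
      utr5 <- .rand_nt(sample(config$utr5_range[1L]:config$utr5_range[2L], 1L))
      utr3 <- .rand_nt(sample(config$utr3_range[1L]:config$utr3_range[2L], 1L))
      seqs[i] <- paste0(utr5, cds, sample(STOP_CODONS, 1L), utr3)
      cds_start <- nchar(utr5) + 1L
      cds_end <- nchar(utr5) + nchar(cds)
    }
    strand <- "+"
    if (i %in% anti_idx) {
      L <- nchar(seqs[i])
      seqs[i] <- revcomp(seqs[i])
      tmp <- L - cds_end + 1L
      cds_end <- L - cds_start + 1L
      cds_start <- tmp
      strand <- "-"
    }
    man$source_gene_symbol[i] <- prot$gene_symbol[g]
    man$source_protein_id[i] <- prot$id[g]
    man$true_cds_start[i] <- cds_start
    man$true_cds_end[i] <- cds_end
    man$strand[i] <- strand
    man$n_substitutions[i] <- mut$n_sub
    man$n_indels[i] <- mut$n_indel
    man$truncation[i] <- trunc
  }
  if (n_decoy > 0L) {
    rng <- 3L * config$protein_len_range
    for (i in (n_coding + 1L):n_tr) {
      seqs[i] <- .rand_nt(sample(rng[1L]:rng[2L], 1L))
      man$origin[i] <- "decoy"
    }
  }
  ord <- sample(n_tr)
  list(transcripts = seq_records(id = ids[ord], seq = seqs[ord]),
       manifest = man[ord, , drop = FALSE])
}

#' Simulate error-free paired reads from transcripts
#'
#' Fragments are drawn per transcript at the configured fold coverage
#' (expected pairs = coverage * length / (2 * read_length)); mate 1 is
#' the fragment's 5' end, mate 2 the reverse complement of its 3' end.
#' A configured fraction of pairs comes from an unrelated random
#' "genomic" sequence. Qualities are uniformly high (`I`).
#'
#' @param transcripts record data.frame of transcripts.
#' @param config a [sim_config()].
#' @return list with `pairs` (data.frame as from [read_fastq_pairs()])
#'   and `manifest` (`pair_id`, `origin`, `source_id`).
#' @export
simulate_reads <- function(transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config$seed, "reads"))
  rl <- config$read_length
  qual <- strrep("I", rl)
  draw_pairs <- function(seq, n) {
    L <- nchar(seq)
    out <- vector("list", n)
    for (k in seq_len(n)) {
      fl <- round(stats::rnorm(1L, config$fragment_len_mean,
                               config$fragment_len_sd))
      fl <- max(rl, min(L, fl))
      st <- sample.int(L - fl + 1L, 1L)
      frag <- substr(seq, st, st + fl - 1L)
      out[[k]] <- c(substr(frag, 1L, rl),
                    revcomp(substr(frag, fl - rl + 1L, fl)))
    }
    out
  }
  reads <- list()
  origin <- character()
  source_id <- character()
  for (i in seq_len(nrow(transcripts))) {
    L <- nchar(transcripts$seq[i])
    if (L < rl) {
      warning("transcript ", transcripts$id[i],
              " shorter than read length; skipped")
      next
    }
    n <- round(config$coverage * L / (2 * rl))
    if (n < 1L) next
    p <- draw_pairs(transcripts$seq[i], n)
    reads <- c(reads, p)
    origin <- c(origin, rep("transcript", n))
    source_id <- c(source_id, rep(transcripts$id[i], n))
  }
  fc <- config$frac_contaminant_pairs
  n_cont <- if (fc >= 1) stop("frac_contaminant_pairs must be < 1") else
    round(fc / (1 - fc) * length(reads))
  if (n_cont > 0L) {
    genomic <- .rand_nt(10000L)
    p <- draw_pairs(genomic, n_cont)
    reads <- c(reads, p)
    origin <- c(origin, rep("genomic", n_cont))
    source_id <- c(source_id, rep("genomic", n_cont))
  }
  if (length(reads) == 0L) {
    empty <- data.frame(pair_id = character(), id1 = character(),
                        seq1 = character(), qual1 = character(),
                        id2 = character(), seq2 = character(),
                        qual2 = character(), stringsAsFactors = FALSE)
    return(list(pairs = empty,
                manifest = data.frame(pair_id = character(),
                                      origin = character(),
                                      source_id = character(),
                                      stringsAsFactors = FALSE)))
  }
  ord <- sample(length(reads))
  reads <- reads[ord]
  pid <- sprintf("PAIR%06d", seq_along(reads))
  pairs <- data.frame(
    pair_id = pid,
    id1 = paste0(pid, "/1"),
    seq1 = vapply(reads, `[[`, character(1L), 1L),
    qual1 = qual,
    id2 = paste0(pid, "/2"),
    seq2 = vapply(reads, `[[`, character(1L), 2L),
    qual2 = qual, stringsAsFactors = FALSE)
  list(pairs = pairs,
       manifest = data.frame(pair_id = pid, origin = origin[ord],
                             source_id = source_id[ord],
                             stringsAsFactors = FALSE))
}

#' Derive a degraded copy of the proteome as a second annotation set
#'
#' Emulates a lower-quality annotation source: configured fractions of
#' entries get a blank gene symbol, an internal deletion (gap-inducing
#' in downstream alignments) or elevated substitution noise.
#'
#' @param proteome result of [simulate_proteome()].
#' @param config a [sim_config()].
#' @return list with `set` (protein set data.frame with `protein_id`,
#'   `gene_id`, `gene_symbol`, `description`, `seq`) and `manifest`
#'   (per-entry degradation flags).
#' @export
degrade_annotation_set <- function(proteome, config) {
  stopifnot(inherits(config, "sim_config"))
  prot <- proteome$proteins
  set.seed(.sub_seed(config$seed, "degrade"))
  n <- nrow(prot)
  pick <- function(frac) {
    k <- round(frac * n)
    if (k > 0L) sort(sample(n, k)) else integer()
  }
  blank <- pick(config$frac_blank_symbol)
  dele <- pick(config$frac_deletion)
  noisy <- pick(config$frac_elevated_sub)
  seqs <- prot$seq
  for (i in dele) {
    L <- nchar(seqs[i])
    dl <- sample(config$deletion_len_range[1L]:config$deletion_len_range[2L], 1L)
    dl <- min(dl, L - 2L)
    st <- sample(2:(L - dl), 1L)
    seqs[i] <- paste0(substr(seqs[i], 1L, st - 1L),
                      substr(seqs[i], st + dl, L))
  }
  for (i in noisy) {
    seqs[i] <- .mutate_protein(seqs[i], config$degrade_substitution_rate,
                               0)$protein
  }
  symbols <- prot$gene_symbol
  symbols[blank] <- ""
  set <- data.frame(protein_id = sprintf("SETB_P%04d", seq_len(n)),
                    gene_id = sprintf("SETB_G%04d", seq_len(n)),
                    gene_symbol = symbols,
                    description = paste0("degraded copy of ", prot$id),
                    seq = seqs, stringsAsFactors = FALSE)
  manifest <- data.frame(protein_id = set$protein_id,
                         source_protein_id = prot$id,
                         blank_symbol = seq_len(n) %in% blank,
                         has_deletion = seq_len(n) %in% dele,
                         is_noisy = seq_len(n) %in% noisy,
                         stringsAsFactors = FALSE)
  list(set = set, manifest = manifest)
}

#' Run every generator and return all synthetic inputs
#'
#' @param config a [sim_config()].
#' @return list with `proteome`, `single_isoform`, `transcripts`,
#'   `transcript_manifest`, `reads`, `read_manifest`, `set_b`,
#'   `set_b_manifest`.
#' @export
simulate_all <- function(config) {
  pr <- simulate_proteome(config)
  tr <- simulate_transcripts(pr, config)
  rd <- simulate_reads(tr$transcripts, config)
  sb <- degrade_annotation_set(pr, config)
  list(proteome = pr$proteins, single_isoform = pr$single_isoform,
       transcripts = tr$transcripts, transcript_manifest = tr$manifest,
       reads = rd$pairs, read_manifest = rd$manifest,
       set_b = sb$set, set_b_manifest = sb$manifest)
}

#' Write all synthetic inputs to a directory
#'
#' Produces `orthologs.fa`, `single_isoform.txt`, `transcripts.fa`,
#' `reads_R1.fastq`/`reads_R2.fastq`, `setB.fa`, `setB_meta.tsv` and
#' `truth_manifest.tsv` under `out_dir`.
#'
#' @param sim result of [simulate_all()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_sim_outputs <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_fasta(sim$proteome, fp("orthologs.fa"))
  writeLines(sim$single_isoform, fp("single_isoform.txt"))
  write_fasta(sim$transcripts, fp("transcripts.fa"))
  write_fastq_pairs(sim$reads, fp("reads_R1.fastq"), fp("reads_R2.fastq"))
  write_fasta(seq_records(id = sim$set_b$protein_id, seq = sim$set_b$seq,
                          description = sim$set_b$description),
              fp("setB.fa"))
  utils::write.table(sim$set_b[, c("protein_id", "gene_id", "gene_symbol",
                                   "description")],
                     fp("setB_meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$transcript_manifest, fp("truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$read_manifest, fp("read_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
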