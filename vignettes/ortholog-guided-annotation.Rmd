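---
title: "Ortholog-guided annotation of de novo assembled transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog-guided annotation of de novo assembled transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transannot)
```

## The problem

When a species has no finished, well-annotated genome but a close
relative does, a *de novo* assembled transcriptome can be annotated by
leaning on the relative's protein set. The motivating use case is a
great-ape transcriptome: mRNA-seq reads from primary cell lines are
filtered for genomic contamination, assembled into contigs, and each
contig's coding sequence (CDS) is located by aligning the contig against
the related species' reference proteins. A contig is annotated only when
a *full-length* CDS can be called — both a start and a stop codon are
present and the conceptually translated protein closely matches its
ortholog. The resulting protein set can then be compared, quantitatively,
against an existing genome annotation to ask which source is more
consistent with the reference proteome.

`transannot` implements that processing chain as a tested, reusable R
package with four analysis stages and a fully seeded synthetic-data
generator, so every stage can be validated against ground truth:

1. **Read filtering** (`filter_pairs`): keep read pairs whose best
   alignment to a reference mRNA set has a reported length inside an
   inclusive window, and remove a read when its mate is removed.
2. **Contig statistics** (`contig_stats`): N50 and mean contig length.
3. **CDS annotation** (`annotate_transcripts`): six-frame translated
   alignment against ortholog proteins, extension to start/stop codons,
   and acceptance thresholds on identity and protein length difference.
4. **Annotation comparison** (`compare_to_reference`,
   `single_isoform_overlap`, `missing_genes`): best-hit percent
   identity, percent similarity and gap counts of two protein sets
   against a common reference proteome.

Assembly itself (de Bruijn graph construction and transcript traversal)
is deliberately out of scope: the pipeline consumes contig FASTA from
any assembler, and the simulator emits contigs directly.

## Alignment engines

The three alignment modes that the original tooling delegated to
BLASTn/BLASTx/BLASTp are provided as exact Smith–Waterman local
alignment with affine gaps (a gap run of length $k$ costs
$\mathrm{open} + k\cdot\mathrm{extend}$), computed by
`Biostrings::pairwiseAlignment`:

* `align_local_nt` — nucleotide vs nucleotide; defaults match +2,
  mismatch −3, gap open 5, gap extend 2.
* `align_translated` — a nucleotide query is translated in all six
  frames; each frame is split into stop-free segments that are aligned
  independently (so a hit can never span an in-frame stop, mirroring
  BLASTX), and query coordinates are mapped back to nucleotides on the
  input strand with `q_start > q_end` on minus frames.
* `align_protein` — protein vs protein with BLOSUM62, gap open 11,
  extend 1, and a `max_targets` cap mirroring `max_target_seqs`.

Exact dynamic programming is a superset of heuristic BLAST in
sensitivity and is fully testable: the test suite checks every engine
against an independently written brute-force Gotoh scoring oracle on
hundreds of random instances, and re-derives every reported column
count (identity, positives, gaps, gap opens) directly from the returned
alignment rows. Because co-optimal alignments exist, the oracle pins the
*score* while the column counts are verified against the alignment the
engine actually reports.

E-values are not computed in-process: the procedure ranks hits by raw
score with a deterministic tie-break (more identical columns, then the
lexicographically smallest subject id) so pipelines are reproducible.
For large inputs, externally computed BLAST tabular files (outfmt 6,
optionally extended with `positive` and `gaps` columns) are accepted via
`parse_blast_tabular` behind the same hit interface.

`N` is allowed in nucleotide input; codons containing `N` translate to
`X`, and `N` never counts as an identity match, not even against itself.

## Read filter

The filter policy keeps a read when its best reference-mRNA alignment
length lies in the inclusive window `[min_len, max_len]`, by default
`[100, 102]` for 101-bp reads — essentially full-length mRNA matches,
with one column of slack on either side for a single indel. Two
decisions were genuinely open:

* *Unaligned reads.* The stated rule addresses only reads with a
  reported alignment, but the filter's purpose is to remove genomic
  contamination, and unaligned-to-mRNA reads are exactly the suspect
  class. The default therefore removes them (`drop_unaligned = TRUE`),
  exposed as a policy flag.
* *"Alignment length".* The BLAST `length` column counts all aligned
  columns including gaps; that convention is adopted, and the length is
  taken from the single best hit, not from any hit.

Mate propagation is a single pass: a pair is removed as soon as either
read fails, so removal cannot cascade. The filter report partitions all
removed reads into out-of-window, unaligned, and removed-via-mate, which
makes the accounting identity
$2(\mathrm{pairs_{in}} - \mathrm{pairs_{kept}})$ = sum of the three
counts testable on every run.

Inside `run_pipeline`, reads are matched against the contig set with an
exact-substring prefilter (`Biostrings::matchPDict` on both strands,
possible because reads have constant width) and only reads without an
exact match fall back to Smith–Waterman. For genuine mRNA reads an exact
full-length match is the overwhelmingly common case, so this is purely
an engineering optimization; the fallback keeps the behavior correct for
divergent reads.

## CDS annotation

The best translated hit seeds the CDS call, which `derive_cds` completes
on the hit's strand and frame:

* extend upstream codon-by-codon from the hit start until an `ATG` is
  found; hitting an in-frame stop or the sequence edge first rejects the
  transcript as `no_start`;
* extend downstream from the hit end to the first in-frame stop;
  reaching the 3' edge first rejects as `no_stop`;
* the CDS is `[ATG .. last sense codon]`, excluding the stop codon, with
  coordinates reported 1-based inclusive on the forward strand.

Extension is the design decision that reconciles two constraints: CDS
ranges come from local translated alignments, yet only transcripts with
*both* start and stop codons qualify — and local alignments rarely
terminate exactly at `ATG` or at a stop. A literal no-extension mode
(`extend = FALSE`) is available for comparison.

A candidate is accepted when the derived protein aligns to its ortholog
with percent identity ≥ 85 and the protein length difference is ≤ 10
residues; both thresholds are *inclusive* (85.0% and 10 pass; the test
suite asserts the boundary). Identity is computed from a fresh
protein–protein alignment of the derived protein against the ortholog,
as `100 * n_identical / alignment_length` — the rule is phrased on the
conceptually derived protein, not on the original nucleotide-level hit,
and the alignment length is used as the denominator (the full ortholog
length would conflate identity with truncation, which the separate
length-difference threshold already handles). Rejection reasons are
assigned in a fixed order (structural — `no_hit`, `no_start`, `no_stop`,
`internal_stop` — before `identity_below`, before `length_diff_above`)
so reports are deterministic.

Summaries count unique proteins by exact string equality of the derived
protein and unique genes by case-sensitive ortholog gene symbol; both
tallies are reported because the deduplication key of the original
counts is not uniquely determined.

The default minimum translated-hit score (`min_hit_score = 50`, raw
BLOSUM62 score) plays the role of BLAST's reporting threshold: genuine
orthologous CDS hits score in the hundreds to thousands, while spurious
local matches of non-coding sequence rarely clear 50; transcripts whose
best hit falls below it are rejected as `no_hit`. Decoys that do clear
it are still rejected downstream by the identity or length-difference
thresholds.

## Annotation-set comparison

`compare_to_reference` aligns each protein of a set against the
reference proteome, keeps the single best hit, and averages percent
identity, percent similarity (columns with a positive BLOSUM62 score)
and gap count over the proteins *with* a hit; proteins with no hit are
counted but excluded from means, which matches how means over BLAST
output behave (absent rows simply do not contribute). "Number of gaps"
is reported as total gap characters per alignment (the BLAST `gaps`
column); gap opens are carried alongside in the per-protein table since
the term is ambiguous in prose.

`filter_by_symbol` drops entries with a blank gene symbol;
`single_isoform_overlap` restricts two summaries to gene symbols present
in both and in a supplied single-isoform list (an input file, as in the
original study, not something the package computes), with the
best-identity row representing a gene when a set has several proteins
for it; `missing_genes` lists symbols of one set absent from the other's
with-hit rows.

## The synthetic-data generator

`sim_config` + `simulate_all` generate a complete labeled study:

* a proteome of `n_genes` random proteins (default 50, lengths uniform
  on 100–500 residues, always starting with M, never containing a stop),
  with gene symbols and a single-isoform flag on a seeded subset;
* transcripts built by reverse-translating each (optionally mutated)
  protein with uniform synonymous codon choice, wrapped in an `ATG`-led
  CDS, a random stop codon, and random UTRs (defaults 20–200 nt 5',
  50–300 nt 3'). Substitutions and indels are applied at the amino-acid
  level and then reverse-translated, so identity percentages against the
  source protein are directly interpretable and `indel_rate = 0`
  guarantees an intact reading frame. A configured fraction are decoys
  (random sequence, default 20%), truncated (missing start or stop,
  default 10% of coding), or emitted antisense (default 50%, since
  assemblers report arbitrary strand);
* error-free 101-bp read pairs at a configured fold coverage (expected
  pairs per transcript = coverage × length / (2 × read length)), with a
  configured fraction of pairs drawn from an unrelated random "genomic"
  sequence (default 10%) and constant `I` qualities — the pipeline never
  uses qualities;
* a degraded copy of the proteome as a second annotation set: 10% blank
  gene symbols, 10% entries with an internal deletion (3–10 residues,
  gap-inducing), 10% with elevated substitution noise (5% per residue).

Truncated transcripts are constructed so their labels are *provable*:
`no_start` transcripts drop the 5' UTR and initiator (plus any leading
methionines), so upstream extension must hit the sequence edge;
`no_stop` transcripts drop the stop codon and 3' UTR, so downstream
extension must hit the 3' edge.

Every generator draws from its own named substream derived from the
master seed, so adding one generator does not shift another's output,
and all outputs are byte-identical under a fixed seed.

What the simulator does *not* emulate: sequencing errors and quality
decay, codon-usage bias, splicing/isoforms, expression-level variation,
chimeric contigs, and paralogy. Passing tests on synthetic data
therefore demonstrate the correctness of the *procedure* (exact
recovery under zero noise, graceful and monotone degradation under
substitution noise, correct bookkeeping everywhere), not the empirical
performance of heuristic aligners and assemblers on real reads.

## Numerical and degenerate-input choices

* N50 uses the descending-sort cumulative-sum convention with threshold
  ≥ total/2; ties resolve naturally (the reported N50 is always the
  length of some contig). Statistics of an empty contig set are an
  error, not zero. Mean length is kept at full precision and rounded
  only in serialized reports.
* Coordinates are 1-based, fully closed intervals everywhere, matching
  BLAST tabular conventions.
* Local alignments with best score below `min_score` are reported as
  no-hit; an all-mismatch comparison yields an empty alignment and is
  likewise no-hit.
* Score ties (across subjects, frames or segments) break by identical
  count, then subject id — every pipeline output is reproducible
  byte-for-byte under a fixed seed, which the test suite asserts by
  running the full pipeline twice.
* Thresholds are validated at configuration time; unknown configuration
  keys are rejected by name.

## Problem sizes in the test suite

The suite validates the engines on 200 random instances per alignment
mode (sequences ≤ 60 symbols) against the brute-force oracle, N50 on
1,000 random length multisets, the read filter on 1,000 synthetic pairs
plus explicit boundary cases, zero-noise end-to-end recovery on 50 genes
with 20% decoys and 10% truncations, noise monotonicity at substitution
rates 0/0.05/0.10/0.20 on 30 genes, and the comparison stage on a
100-protein degraded set. These sizes exercise every code path while
keeping the default `testthat` run to a few minutes on one core; all
rates and thresholds are the package defaults described above.

## Known limitations

* Annotation is strictly ortholog-guided: transcripts without a
  sufficiently scoring translated hit are never annotated (no ab initio
  ORF calling), and one annotation is made per transcript (best hit
  only).
* The built-in engines compute no E-values; statistical significance
  filtering must come from external BLAST runs when desired.
* Alignment is exact but quadratic; for genome-scale inputs the intended
  route is external BLAST tabular files through `parse_blast_tabular`.
* UTR annotation, isoform reconstruction, and submission-format
  generation are out of scope.
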