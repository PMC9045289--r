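---
title: "Expression-normalized TSS calling: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-normalized TSS calling: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capptss)
```

## The problem

5'-end sequencing protocols for bacteria (Cappable-seq, Capp-Switch seq)
enrich primary transcripts through their 5' triphosphate, so that read 5'
ends pile up on transcription start sites (TSSs) at single-nucleotide
resolution.  In practice the tracks carry a strong background: highly
expressed genes are covered by read starts along their whole body, from
nonspecific initiation and from processed transcripts that survive the
enrichment.  A fixed reads-per-million (RPM) cutoff therefore does two
wrong things at once — it floods highly expressed genes with spurious
intragenic calls, and it misses genuine TSSs of moderately expressed
genes whose signal sits below the cutoff.

The pipeline implemented here removes this bias by *expression
normalization*: every candidate position is associated with a gene, its
RPM is divided by that gene's RNA-seq expression (TPM), and the resulting
values are rescaled to a total of one million, after which one fixed
cutoff applies uniformly across expression levels.

## The pipeline

`call_tss()` composes six stages, in this order:

1. **RPM scaling** (`to_rpm`): each replicate's per-position read-start
   counts are scaled by `1e6 / library_size`.
2. **Replicate intersection** (`intersect_replicates`): only
   (contig, strand, position) triples carrying signal in *both*
   replicates survive; the candidate RPM is the arithmetic mean of the
   replicate RPMs.  A single-replicate mode passes one track through
   unchanged.
3. **Gene association** (`associate_genes`): a candidate inside a gene
   (bounds inclusive) is intragenic with distance 0; otherwise it is
   assigned to the gene minimizing the distance to the nearest gene
   boundary.
4. **Classification** (`classify_tss`): localization crossed with
   orientation gives `InterS`, `InterA`, `IntraS`, `IntraA`.  `InterS`
   additionally requires the gene's translated start to lie downstream
   of the TSS on the shared strand (`upstream_of_cds > 0`); an
   intergenic sense candidate past a gene's 3' end is `InterA`, since a
   promoter position it is not.
5. **Normalization** (`normalize_tss`, skipped in `mode = "raw"`):
   `u_i = rpm_i / max(tpm_gene(i), tpm_floor)`, then
   `normalized_rpm_i = u_i * 1e6 / sum(u)`.
6. **Clustering and thresholding** (`cluster_tss`, `threshold_tss`):
   greedy highest-value peak picking with a 5-bp suppression radius per
   contig and strand, then an inclusive cutoff (25 by default, 10 for
   the permissive set) on the clustered values.

```{r pipeline-example}
experiment <- simulate_tss_experiment(n_genes = 50, sdlog = 1,
                                      depth = 1e6, beta = 0.5, seed = 42)
records <- call_tss(experiment$tracks[[1]], experiment$tracks[[2]],
                    experiment$ann, experiment$rnaseq)
table(records$category)
```

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `window` | 5 | bp | suppression radius of peak clustering; no two reported TSSs on a contig/strand are closer than this |
| `cutoff` | 25 (10 permissive) | normalized RPM | inclusive detection threshold applied after clustering |
| `promoter_len` | 50 | bp | promoter window upstream of the TSS (TSS base excluded) |
| `leaderless_max` | 6 | bp | exclusive bound: a 5' UTR shorter than this is leaderless |
| `conservation_max_dist` | 200 | bp | exclusive bound on TSS-to-start distance for InterS promoters entering conservation |
| `tpm_floor` | 1 | TPM | pseudo-expression for unexpressed/unknown genes |

The clustering/cutoff constants are the standard values for this assay
family; `tpm_floor` exists so that a candidate on a gene with zero
measured expression is divided by a finite value and kept (its inflated
normalized strength makes it easy to filter downstream) rather than
dropped or divided by zero.

## Decisions at genuinely open points

Several details of this pipeline family are conventionally left
unstated; the package fixes them as follows, and tests pin each one.

* **Replicate combination.** Replicate RPMs are *averaged*, not summed:
  the mean keeps the one-million scale of a single library
  interpretable.
* **"5-bp sliding windows".** Clustering is implemented as greedy
  highest-value peak picking with suppression radius `|Δpos| < window`:
  visit candidates in decreasing value (ties: smaller coordinate), and
  accept one unless an already-accepted candidate on the same contig and
  strand is closer than the window.  This is order-independent given the
  priority rule, and an exhaustive priority oracle reproduces it exactly
  in the tests.
* **Cluster, then threshold.**  Thresholding after clustering means a
  strong peak's shoulder positions never pass on their own; the reverse
  order would let a sub-cutoff shoulder suppress nothing while the
  10-RPM set lost nesting with the 25-RPM set.  Output sets are nested
  across cutoffs (10 ⊇ 25).
* **No minimum raw count before intersection.**  None is imposed;
  replicate intersection is the noise gate.
* **Association ties.**  A candidate equidistant from two genes (or
  contained in overlapping genes) prefers the same-strand gene whose
  translated start lies downstream of the candidate — the biologically
  canonical promoter configuration — then the smaller gene start.
  Deterministic, and exercised position-by-position in a truth-table
  test.
* **No maximum association distance.**  Downstream consumers filter
  (the conservation analysis uses `d < 200` bp).
* **Whole-gene TPM.**  Normalization divides by the associated gene's
  whole-gene TPM (the mean across RNA-seq replicates; a single
  replicate is accepted), not by local coverage.

## 5' UTRs, promoters, initiating bases

`utr_length()` measures InterS 5' UTRs as the TSS-to-translated-start
distance along the gene strand; UTRs shorter than 6 bp mark leaderless
transcripts (no room for a ribosome binding site).  `extract_promoters()`
takes the `promoter_len` bases immediately upstream of the TSS — the TSS
base itself is excluded, so a motif found at the promoter's 3' edge abuts
but does not cover the start site; the same convention makes the
exported FASTA reproducible input for motif discovery tools.  Windows
wrap on circular contigs and are clipped (and flagged) on linear ones.
`initiating_base_stats()` reads the genomic base under each TSS on its
strand; bacterial initiation is overwhelmingly purine, so the A+G
fraction is a cheap global sanity check of a called set.

## Degenerate motif scanning

`iupac_scan()` emulates pattern matching in the RSAT *dna-pattern*
style: every aligned base must be compatible with the pattern's IUPAC
code (degeneracy is free), up to `max_indels` insertions plus deletions
are allowed (default 1), and mismatches beyond degeneracy are not.
Matching is implemented by enumerating the pattern's indel variants
(deletion of any position; insertion of an unmatched subject base
strictly inside the pattern) and running each through exact degenerate
matching; a span reachable by several variants keeps its minimal edit
count.  Overlap of successive matches is prevented greedily 5'→3' *on
the scanned strand* — the reverse strand is scanned on the reverse
complement — with exact matches winning ties at the same start.  With
`max_indels = 0` the scanner is provably equivalent to a regular
expression built from the IUPAC table, and the tests check that
equivalence on random kilobase sequences.

## Promoter conservation across strains

For a strain pair, all cross-strain promoter pairs are aligned globally
(Needleman–Wunsch).  Alignment parameters are match +1, mismatch −1,
gap −2, linear gaps — a simple standard scheme for short fixed-length
windows, configurable via `alignment_scoring()`.  Scores split into an
*ortholog* group (gene pairs above 60% identity in the supplied ortholog
table, strict) and a *non-ortholog* null group.  The score threshold is
the 95th percentile of the null distribution — i.e. at most ~5% of
unrelated promoter pairs would pass — chosen because it is reproducible,
monotone in the data, and directly expresses the separation the
distributions are inspected for; the quantile is configurable and the
ortholog pass fraction is reported as a diagnostic.  Matching is greedy
by decreasing score with each promoter used at most once, yielding a
deterministic partial one-to-one pairing; only ortholog-gene pairs are
eligible for matching, the non-ortholog alignments serve purely as the
null.  A three-way strain comparison is realized as the three pairwise
analyses.  Above `max_nonortholog` pairs the null group is subsampled
under the caller's RNG seed.

## The synthetic generator

`simulate_tss_experiment()` produces the entire input side of an
experiment with known ground truth:

* a linear AT-rich (31% GC, clostridia-like) contig of
  alternating-strand genes of fixed length 900 bp spaced 200 bp apart;
* log-normal true expression (`sdlog = 2`), rescaled to one million
  TPM, so a tail of genes exceeds 1,000 TPM — the regime in which raw
  thresholds are visibly expression-biased;
* one planted InterS TSS per gene, at a UTR distance `6 + Poisson(26)`
  (mode near the canonical ~32 bp, always < 200 bp and inside the
  intergenic gap), leaderless with probability 0.025 (UTR 1–5 bp, since
  a 0-bp UTR would sit on the translated start and classify
  intragenic); the initiating base is written into the genome as a
  purine with probability 0.95;
* two replicate read-start tracks, drawn independently: Poisson counts
  with mean `strength × depth` at planted sites (strength
  `0.3 × tpm/1e6`, i.e. promoter output proportional to transcript
  abundance, 30% of reads overall), plus per-gene Poisson background
  scattered uniformly over the gene body on the sense strand with mean
  `depth × beta × (tpm/1e6) × (len/1000)`.  The default `beta = 2`
  makes background ~86% of the library, matching the dominant
  gene-body noise these libraries show in practice;
* matched RNA-seq counts, Poisson with mean proportional to
  `tpm × length`, which invert exactly through `compute_tpm()` in
  deterministic mode.

**Depth.**  The default is `1e7` read starts per replicate.  The genome
here is ~20× smaller than a real bacterial genome, and what matters for
replicate intersection is the per-position count regime: at real
library sizes a full-size genome's expressed positions carry multiple
reads, and intersection then behaves as a noise gate.  Scaling the
genome down while keeping a small library would instead put background
in a sparse regime where isolated single-read positions recurring in
both replicates dominate — a discreteness artifact of the scale-down,
not a property of the assay — so the default depth restores the
read-dense regime.  `beta = 0` gives noiseless tracks for exact tests.

All draws are Poisson (a negative-binomial option was considered and
left out: no overdispersion estimate exists to calibrate it against),
positions are integer arithmetic, and every function is deterministic
given its seed.

**What the generator does not emulate:** sequencing errors and mapping
ambiguity; strand-asymmetric or 5'-biased RNA-seq coverage; operonic
structure (each gene is its own transcription unit); condition-dependent
TSS switching; overlapping genes.  Passing tests therefore demonstrate
the pipeline's arithmetic and its bias-removal mechanism, not
robustness to mapping artifacts or annotation errors.

## Numerical and degenerate-input choices

* Thresholds are inclusive (`value >= cutoff`).
* Clustering ties (equal values) keep the smaller coordinate.
* TPM of an all-zero count table is all-zero (no division); TPMs
  otherwise sum to one million to within 1e-6 relative, as does the
  normalized RPM mass.
* Candidates on contigs with no genes are `unassigned` orphans,
  normalized with `tpm_floor`, and never enter InterS summaries.
* Empty inputs (tracks, candidate sets, TSS tables) propagate as empty
  outputs with intact schemas; an empty sequence aligns to all-gaps with
  score `gap × length(other)`.
* TSS tables are written sorted by contig, position, strand, making
  repeated runs byte-identical.

## Problem sizes in the tests

The test-suite fixtures use 3–200 genes; the full-pipeline bias checks
run the default 200-gene experiment (~2×10^7 read starts per replicate
pair, ~10 s), oracle comparisons run 500 random tracks, 200 random
alignment pairs and 100 random kilobase scans.  These sizes were chosen
to exercise every code path at comfortable interactive speed.

## Known limitations

* Gene association assigns exactly one gene per TSS; divergent
  promoters driving two genes appear once, under the tie rule.
* The conservation threshold assumes enough non-ortholog pairs to
  estimate a 95th percentile; very small promoter sets make it noisy.
* `iupac_scan()` enumerates indel variants, which is exponential in
  `max_indels`; budgets beyond 2 are impractical (and biologically
  questionable for short motifs).
* Motif discovery itself (MEME) and RNA secondary structure are out of
  scope; the package exports promoter FASTA for external tools instead.
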