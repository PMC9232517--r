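---
title: "Methods: classification, families and communication inference in mitopiR"
author: "mitopiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classification, families and communication inference in mitopiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopiR)
```

# Scope and model

`mitopiR` analyses collapsed single-end small RNA reads (15–75 nt) with
respect to two reference genomes — a nuclear assembly and a circular
mitochondrial genome — and two reference sets of small RNAs: a
PIWI-immunoprecipitation-derived piRNA set and a miRNA set. The model
has three layers:

1. **Genome class.** A sequence is placed on each genome by ungapped
   (Hamming) matching with at most `k_genome` mismatches. Hit existence
   defines the class: NUMT (both genomes), MT (mitochondrial only), NU
   (nuclear only), UNMAPPED (neither). The two searches are
   independent; the minimal-mismatch stratum is taken per genome.
2. **Category.** Equal-length bounded-Hamming matching against the
   reference sets gives piRNA, miRNA, dual (both) or other (neither).
3. **Family and direction.** Sequences ≥ `anchor_min` nt that are exact
   5′ prefixes of one another and share a genomic 5′ locus form a
   family. Members matching the piRNA set are mature; a member longer
   than every mature, absent from the set, and fully placed on a genome
   is a precursor (pre-piRNA). For families with at least three counted
   members, at least one precursor, one mature and one MT/NUMT member,
   the direction is a pure function of the member classes:
   *retrograde* when all precursors are MT and some mature is NUMT;
   *anterograde* when all precursors are NU and some mature is NUMT or
   MT; *self* when the family is confined to a single genome;
   *unresolved* otherwise.

## Assumptions

* Reads are adapter-trimmed; quality content is not used. A minimal 3′
  adapter clip (`clipAdapter()`) is provided as plumbing only.
* No indels: a biological sequence either matches a genomic window
  position-for-position or it does not. This is the natural model for
  short reads placed with an ungapped `-v`-style aligner.
* Reference-set membership is equal-length: a 24-mer entry never
  certifies a 30-mer query. The precursor/mature distinction depends on
  this strictness; prefix relations are handled by the family layer,
  not the matcher.
* The D-loop and replication origin are strandless regions; their
  orientation baseline is the forward reference strand. Stranded
  features (tRNA, rRNA, CDS) use their annotated strand, so a read is
  *forward* when it runs with its feature's sense.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `k_genome` | 1 | mismatches | tolerates one polymorphism/sequencing error per genome placement |
| `k_pirna` | 1 | mismatches | strict piRNA identity |
| `k_mirna` | 2 | mismatches | conventional, slightly looser miRNA matching |
| `cpm_threshold` | 10 | counts per million | discards sequences *under* 10 CPM in every sample; exactly 10 is kept |
| `anchor_min` | 20 | nt | lower bound of canonical mature piRNA length; shorter sequences cannot anchor a family |
| `require_shared_locus` | TRUE | — | prefix-related sequences must share (genome, contig, strand, 5′ coordinate); disables chance prefix collisions across loci |
| `lmax` (bias profile) | 35 | nt | upper bound of canonical piRNA length; longer sequences contribute to positions 1–35 only |

The CPM denominator is the per-sample total of trimmed reads entering
collapse (after dropping ambiguous reads), so pre-filter CPM sums to
10⁶ per sample exactly. The retention rule is cross-sample: a sequence
is kept when it reaches the threshold in *any* sample, with per-sample
membership flags retained so per-sample tallies remain reproducible.
Whether filtering should be per sample or pooled is genuinely open; the
any-sample rule reconciles per-sample tables with cross-sample
matrices and is flagged in the per-sample `retainedIn` assay.

## Coordinates and circularity

All external coordinates are 1-based inclusive. Placements are
5′-anchored: `start` is the position of the read's 5′ end on the
forward coordinate system (for minus-strand placements, the higher
coordinate of the covered interval). This convention makes the shared
anchor of a trimming family a single number and lets
`spanLength(a, b)` = |a − b| + 1 reproduce printed feature spans. The
mitochondrial genome is circular: the search extends the sequence by
its first (query length − 1) bases, and coordinates are reported modulo
the genome length; junction-spanning reads are first-class citizens.

## Expression attribution

A sequence with several minimal-stratum mitochondrial placements has
its counts divided equally among them, and each placement's share is
split across overlapped features proportionally to overlapped bases
(the uncovered remainder is intergenic). Totals are therefore conserved
exactly — feature tables and strand matrices sum to the mitochondrial
totals — at the cost of fractional attribution for multi-mapping
sequences. This choice avoids double counting; the alternative
(winner-takes-all by largest overlap) changes only boundary-straddling
reads.

## Sample PCA

The PCA input is the strand-resolved CPM matrix, log2(x+1)-transformed
and row-centred, decomposed by SVD. The source study does not specify
its PCA matrix; this choice is ours and is recorded as such. Components
are sign-fixed by making each component's largest-magnitude loading
positive, so results are fully deterministic. With identical columns
the decomposition is degenerate and explained variances are reported as
zero.

# The synthetic-data generator

The generator is first-class, tested code. It emulates the study
conditions the pipeline targets:

* a 16,299-nt circular mitochondrial genome with 22 tRNAs (mixed
  strands), 2 rRNAs (forward), 13 protein-coding genes (one reverse),
  one replication origin, and a D-loop pinned at the high-coordinate
  end;
* nuclear contigs (100 kb total by default) carrying 12 NUMT
  insertions of 120–400 nt, the first sourced from the D-loop, with a
  per-base substitution divergence of 0.02 by default (0 in recovery
  experiments, where truth must be exact);
* 10 planted piRNA families with ladder 60/30/28/25 nt in a 70/20/10
  retrograde/anterograde/self mix. Locus placement realises the
  direction by construction: retrograde precursors sit in mtDNA with
  matures inside a NUMT source; anterograde precursors sit in a NUMT
  copy and run into unique nuclear flank; self families avoid NUMTs
  entirely. One family per NUMT, and the planted D-loop family is
  antisense to the reference, matching the observation that D-loop
  piRNAs are reverse-oriented;
* a 12-sample design grid (PGC/SC × F/M × 11.5/12.5/13.5 dpc) with
  100,000 reads per sample by default — a desk-scale stand-in for
  ~10 M-read libraries — drawn by per-sample multinomial over
  lognormal expression weights shared across samples. The lognormal is
  a stand-in choice; no expression-magnitude distribution is implied by
  the underlying biology;
* 300 background loci with distinct 5′ positions (so no accidental
  prefix family can form and the planted family count is exact), a
  read-level binomial first-position adenine bias (0.8) on background
  reads, and D-loop loci that emit antisense to the reference with
  probability 1 by default. The antisense decision is made per locus at
  pool construction so that the adenine bias applies to the emitted
  sequence; at the extreme settings used for validation (fraction 1)
  this is indistinguishable from a per-read decision;
* 20 noise sequences and reference-set decoys, each certified by a
  brute-force scan to sit at Hamming distance ≥ 2 from both genomes,
  so they can never confound classification;
* truth classes derived from generator bookkeeping (NUMT
  source/copy intervals plus recorded substitution positions), exact at
  zero divergence. Background windows straddling a source/copy boundary
  are rejected during sampling, because a short overhang could match
  the other genome within the mismatch budget and make bookkeeping
  truth unreliable.

Identical configurations (including the seed) produce byte-identical
outputs; every stochastic stage draws from a named sub-stream of the
master seed, so adding a stage never shifts another stage's draws.

## What the generator does not emulate

Sequencing errors, adapter contamination, quality-score structure,
isomiR-style length variation in the reference sets, ping-pong
signatures, and realistic genome-wide repeat structure. Passing the
recovery experiments therefore demonstrates the correctness of the
pipeline's logic under its stated model — not robustness to alignment
artefacts or repeat-induced ambiguity in a real genome.

# Numerical and degenerate-input choices

* Family representative ties (equal longest length) break
  lexicographically.
* Empty inputs: collapsing an empty read set yields an empty container
  with zeroed statistics (not an error); an empty family set reports a
  direction summary flagged `empty` with denominator zero.
* Bias profiles error (naming the subset) on empty subsets instead of
  returning NaN matrices.
* Boundary CPM: retention uses `>=`, because the rule discards
  sequences *under* the threshold.
* Direction percentages are over resolved, eligible families
  ({retrograde, anterograde, self}); unresolved families are reported
  separately, never silently dropped. Each family counts once per
  cohort, not once per sample.
* Hits export to BED6 converts 1-based inclusive, 5′-anchored
  placements to 0-based half-open intervals at the writer; circular
  junction-spanning hits split into two lines.

# Problem sizes

The test suite exercises a small cohort (12 × 3,000 reads, 30–50 kb of
nuclear sequence) for unit-level checks and one full-scale recovery run
(12 × 100,000 reads, 10 families, zero divergence) for the end-to-end
guarantees; `scripts/acceptance.R` repeats the full-scale run from
scratch. These sizes keep a complete validation under a few minutes on
one CPU while leaving every rule of the method exercised at the same
parameter values that a real analysis would use.

# Known limitations

* Hamming-only placement cannot place reads over indel polymorphisms.
* Equal-length reference matching will miss isomiR-like variants; dual
  calls are not validated against hairpin structure.
* The eligibility rule needs a detected precursor: families whose
  precursor falls under the CPM threshold are unresolved even when the
  matures are abundant.
* Truth bookkeeping at nonzero NUMT divergence is approximate near
  substituted positions, which is why recovery experiments fix
  divergence at zero and report divergence runs as stochastic
  tolerances rather than exact matches.
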