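---
title: "Evaluating and merging de novo transcriptome assemblies"
author: "txConsensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and merging de novo transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Motivation

When no reference genome exists, a transcriptome must be assembled de novo
from RNA-seq reads. Different assemblers, and different k-mer settings
within one assembler, reconstruct overlapping but distinct transcript
sets: low k favors lowly expressed transcripts, high k favors highly
expressed ones, and every tool contributes private artifacts. A practical
answer is consensus: evaluate several single-k (SK) and multiple-k (MK)
assemblies with a common set of metrics, select one assembly per tool, and
merge the selections into a set of *robust* contigs — consensus sequences
whose constituents were produced independently by several tools. This
package implements that workflow end to end for desk-scale data, with a
seeded simulator so every step can be exercised and tested without any
external dataset or external assembler.

The assemblers themselves are integration points, not dependencies: the
pipeline consumes their FASTA outputs through a label map (file, tool, k).

# The processing model

## Read quality control

Each read's qualities are decoded from Phred+33 (an explicit flag switches
to +64; no auto-detection, because silent auto-detection makes trimming
irreproducible). Trimming follows the cumulative-error rule: with error
probability $e_i = 10^{-Q_i/10}$ at base $i$ and a limit $\ell$ (default
0.05), the running total

$$s_i = \max(0,\; s_{i-1} + (\ell - e_i)), \qquad s_0 = 0$$

is clamped at zero; the retained segment starts at the first position of
the final positive run and ends at the position of the maximum of $s$. If
the maximum is attained more than once we keep the *last* such position —
the rule's source says only "end at the highest value", and retaining more
sequence is the conservative reading. The implementation evaluates the
recursion through the closed form $s_i = c_i - \min(0, \min_{j \le i}
c_j)$ with $c_i = \sum_{j\le i}(\ell - e_j)$; the test suite checks it
against a literal step-by-step simulation on a thousand random quality
strings.

After trimming, a read is discarded if shorter than 20 bases or if it
retains more than 2 ambiguous bases. Duplicate removal treats a *pair* as
the unit: the ordered tuple (mate1 sequence, mate2 sequence) must match
exactly; orphans match on exact sequence. No reverse-complement collapsing
and no quality comparison — the vendor tool's internal definition is not
public, so the package states the minimal reproducible one. Finally only
reads strictly longer than 50 bp are kept. The stage order trim →
duplicates → length filter is fixed, and the accounting table reports
reads in pairs, orphans and their sum at each stage, with pair-breaks
(one mate removed) converting pairs into orphans.

Subsampling draws a uniform random subset of *pairs* without replacement
(orphans are excluded, matching the workflow's "30 million paired reads"
usage); the complement is returned so that unselected reads can validate
an assembly built from the selected ones. The generator
(Mersenne-Twister) and seed are recorded in the result.

## Evaluation metrics

For an assembly, statistics are computed over contigs strictly longer
than 200 bp: contig count, total bp, mean length, N50 (largest length L
such that contigs of length at least L cover at least half the total —
the community convention, since the source never defines it), and the
number of contigs strictly longer than 1 kb. Two further columns complete
the evaluation row: RMBT, the percentage of validation reads mapping
end-to-end to the contigs, and the core-gene completeness pair
(complete % / partial %).

k selection operationalizes "maximize N50 while keeping the total
assembly length as long as possible" as a Pareto filter: among candidates
whose total length is at least a fraction $f$ (default 0.90) of the
largest candidate total, pick the k with the highest N50, ties to the
smaller k. The fraction is exposed because the source states no rule; a
tunable filter makes the heuristic reproducible.

## Redundancy removal

Within one assembly, shorter transcripts sharing more than 99% identity
with a longer one are removed by greedy longest-first clustering, and
survivors at or below 200 bp are dropped. Identity is the global-alignment
match count divided by the length of the shorter sequence, both strands
considered — the containment-collapsing convention of the usual
nucleotide clustering tool. For speed, an exact ungapped diagonal bound
(shared-word diagonals, byte comparison) settles clear cases, and the
dynamic-programming alignment decides only candidates in a narrow band
(within 0.05) below the threshold, where gapped alignments could still
cross it; a banded window around the best diagonal keeps that alignment
small. Candidate pairs come from a global shared-word count with a
pigeonhole lower bound (each of at most $e$ edits can destroy at most $w$
words, halved again as slack), so the prefilter cannot change the result
relative to exhaustive comparison; the tests verify clustering against an
alignment-only oracle.

## Reads mapped back to transcripts

RMBT treats the mapper as a yes/no validity check, so the package uses an
auditable substitute for an external aligner: gapless end-to-end
alignment with a mismatch budget of $\lfloor 0.04 \cdot \text{len}
\rfloor$. Candidate loci come from an exact k-mer index; the seed width is
chosen so that a read carrying the full budget must still contain one
exact seed (pigeonhole over budget+1 disjoint seeds), making candidate
generation exhaustive with respect to the budget. Among hits, fewest
mismatches wins, ties going to the first transcript id, then position,
then plus strand; multi-mappers count once, and mates are counted as
individual reads. A SAM adapter (mapped = FLAG 0x4 unset, primary records
only) lets an external end-to-end mapper stand in when real data are at
hand.

## Core-gene completeness proxy

The original methodology scores transcriptome completeness with an
HMM-based core-gene pipeline. That machinery is out of scope here; the
package preserves the metric's role with a nucleotide-space proxy: each
user-supplied core gene is aligned locally against every transcript (both
strands; shared 12-mer prefilter), and the best coverage of the gene by a
*single* transcript at identity at least 0.95 classifies it as complete
(coverage ≥ 0.70, the core-gene tool's published convention), partial
(≥ 0.30, a declared stand-in for that tool's internal cutoff) or absent.
Partial percentages include complete genes, so partial ≥ complete, as in
the original reports. Coverage is never stitched across transcripts for
the status call — one intact gene model is the spirit of "complete" — but
a stitched-coverage column (union of qualifying intervals over all
transcripts) is reported as supplementary information. Exact diagonal
matches settle clear cases; the DP local alignment runs only when
diagonals are indecisive, in a window around the supporting diagonal, and
is skipped (diagonal answer stands) when the DP would exceed about 25
million cells — a documented sensitivity/efficiency trade-off for gapped
hits between very long sequences.

## Consensus merging and robust contigs

Merging replaces the external overlap-layout program with a native greedy
merger whose defaults mirror that program's documented ones: overlaps of
at least 40 bp at at least 90% identity. Input contigs are pooled with
namespaced ids (`tool_k_origid`) so provenance survives any merge.
Candidate overlaps come from shared-word diagonal voting (word size grows
from 8 to 12 with pool size to bound the all-versus-all join); each
surviving diagonal is scored exactly by byte comparison. Diagonals whose
shared-word support is far below what 90% identity implies (fewer than
one word per 20 overlap positions) are not evaluated — an explicit
detection heuristic, adequate because both simulated and real near-exact
overlaps carry dense exact words, but a worst-case adversarial mismatch
spacing at long overlap lengths could evade it. Gapped overlaps are not
modeled: the simulator introduces substitutions only, and indel-bearing
overlaps in real data would be better served by the external-program
adapter.

Edges are processed best-identity-first, then longest-first; a union-find
layout assigns each contig a strand and offset in its cluster, composing
coordinate transforms through the connecting edge; later edges within an
already-joined cluster are skipped. The consensus is the column-majority
base over the laid-out constituents, ties resolved by the longest
constituent covering the column. Every input contig ends up in exactly
one merged contig's constituent list (singlets included), which the tests
assert as conservation.

A merged contig is *robust* when its constituents come from at least
`minTools` distinct tools (default 3, "assembled by three different
tools"); a strict mode instead requires every input assembly to
contribute, covering the stricter "present in all original assemblies"
reading — which of the two the original intended is ambiguous, so both
are provided. Tools are counted, not assemblies: two k-values from one
tool count once. Singlets are never robust for `minTools` > 1. After
robust filtering the pipeline re-applies the 99% redundancy rule and the
strict >200 bp rule, since reported statistics are defined over
non-redundant sequences greater than 200 bp.

# The simulator: what it emulates, and what it does not

`simulateTranscriptome` / `simulateReads` / `simulateToolAssemblies`
generate the stated world the tests run in:

* 100 bp paired-end reads (the protocol's read length) with insert size
  Normal(305, 30) rounded and truncated to [read length, transcript
  length] — 305 is the insert the original analysis passed to its
  assembler; the 30 bp spread is a realistic library width chosen once
  here.
* transcript lengths log-normal(meanlog 7, sdlog 0.6) truncated to
  [200, 10000] bp (median about 1.1 kb, as for vertebrate mRNA), with
  log-normal(0, 1.5) expression weights, so coverage varies with
  expression as it does in RNA-seq.
* per-base substitution errors (default 0.005) with quality strings that
  are constant Q38 except Q12 at simulated error positions, giving the
  trimmer genuine signal; fragments are drawn with probability
  proportional to weight times the number of eligible start positions.
* per-tool corruption: dropout, fragmentation into two overlapping
  pieces (overlap at least 50 bp), contig substitution errors, and
  tool-private random noise contigs; every simulation returns its ground
  truth map.

Not emulated: GC/hexamer/positional bias, splicing and isoforms, PCR
duplicates, indel errors, and codon structure (bases are uniform). A
green test therefore establishes the *logic* of trimming, clustering,
mapping, merging and accounting on the stated world — not performance on
real libraries, where the external-tool adapters (SAM input, merge-output
ingestion via the label map) are the intended route.

# Numerical choices and degenerate inputs

* Trimming ties take the last argmax; an all-bad read returns an empty
  interval and is discarded. Strict inequalities everywhere the source
  prints one (">50 bp", ">200 bp", ">1 kb").
* `n50` errors on empty input; `assemblyStats` errors when nothing
  survives the length filter; `rmbtPercent` errors on zero reads —
  silent NaNs would corrupt report tables.
* All randomness flows from one top-level integer seed; derived seeds are
  small fixed offsets of it. Re-running a pipeline with the same config
  and seed reproduces the TSV reports byte for byte.
* The RMBT validation stage caps the mapped reads (default 20,000, a
  seeded subsample of the unselected reads) so desk-scale runs stay fast;
  the cap is a performance parameter, reported in the log, and can be set
  to `Inf`.

# Known limitations

* The merger's consensus assumes ungapped layouts; a constituent with an
  indel would shift downstream columns (majority voting then repairs
  isolated columns only).
* The completeness proxy is nucleotide-space: genes diverged beyond 95%
  nucleotide identity from their transcripts (e.g. cross-species use)
  will read as absent even when a protein-space HMM would find them.
* Overlap detection and clustering prefilters trade worst-case
  adversarial sensitivity for speed, as documented above; both are exact
  on the simulator's substitution-only error model.
* The pipeline is single-threaded and desk-scale (about 10^3–10^4
  contigs, 10^5 read pairs); it does not target cluster-scale inputs.
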