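# txConsensus

Consensus evaluation and merging of de novo transcriptome assemblies.

For organisms without a reference genome, transcriptomes are assembled de
novo from RNA-seq reads — and every assembler, and every k-mer setting,
reconstructs a somewhat different transcript set. This package is for
researchers who want to compare such assemblies on common ground and
distill them into a set of *robust* contigs: consensus sequences supported
independently by several tools. It implements, self-contained and
desk-scale:

* **Read QC** — quality trimming by cumulative error probability
  (limit 0.05: the running total of `limit − 10^(−Q/10)` is clamped at
  zero; the retained segment runs from the first positive value to the
  maximum), an ≤2-ambiguous-base rule, a 20 bp minimum trimmed length,
  pair-aware exact duplicate removal, a strict >50 bp keep filter, and a
  per-stage accounting table (pairs / orphans / sum).
* **Seeded subsampling** of read pairs without replacement; the unselected
  complement serves as validation reads.
* **Evaluation metrics** over contigs >200 bp: count, total bp, mean
  length, N50 (largest L with contigs ≥ L covering ≥ half the total),
  contigs >1 kb, RMBT (% of reads mapping back end-to-end, ≤4% mismatches,
  no gaps or clipping), and a core-gene completeness proxy
  (complete ≥70% / partial ≥30% single-transcript coverage at ≥95%
  identity).
* **k selection** — among candidate single-k assemblies within 90% of the
  maximal total length, pick the highest N50 (ties to smaller k).
* **Redundancy removal** — greedy longest-first clustering at >99%
  identity (identity = global-alignment matches / shorter length, both
  strands, so containments collapse), then keep >200 bp.
* **Consensus merging** — pooled contigs with provenance
  (`tool_k_origid`), greedy overlap-layout merging (≥40 bp, ≥90% identity,
  both orientations), column-majority consensus, and the robust-contig
  filter (constituents from ≥3 distinct tools; strict all-assemblies mode
  available).
* **A seeded simulator** — ground-truth transcriptomes, 100 bp paired-end
  reads (insert 305 ± 30), expression-dependent coverage, error/quality
  model, and per-tool corrupted assemblies (dropout, fragmentation, noise
  contigs) with full truth maps.

External assemblers are integration points, not dependencies: the pipeline
consumes their FASTA outputs via a label map (file, tool, k).

## Worked example

Simulate a 60-transcript ground truth with three corrupted "tool"
assemblies, then run the full workflow:

```r
library(txConsensus)

fx <- simulateDataset("demo/data", simConfig(nTranscripts = 60, seed = 7),
                      nPairs = 5000)
conf <- pipelineConfig(fx$reads1, fx$reads2, fx$assemblies, "demo/out",
                       coreGenes = fx$coreGenes, subsampleN = 2000,
                       seed = 7)
res <- runPipeline(conf, quiet = TRUE)
print(res$metrics, digits = 4)
```

```
    tool      k n_transcripts total_bp mean_len  n50 n_long rmbt_pct
1  alpha    sim            94   101271     1077 1455     35    98.70
2   beta    sim            91   100693     1107 1452     36    99.18
3  gamma    sim            92   100710     1095 1359     38    98.98
4 merged robust            60    90126     1502 1718     38    99.95
  cegma_complete_pct cegma_partial_pct
1              86.67               100
2              90.00               100
3             100.00               100
4             100.00               100
```

Each per-tool assembly carries ~30 fragmented transcripts and 20 private
noise contigs, so it shows ~94 contigs and incomplete core-gene recovery
(fragments cover <70% of their gene). The merged robust set recovers
exactly the 60 true transcripts: noise contigs never gather support from
three tools, fragment pairs merge back into full-length consensus contigs
(mean length and N50 rise), 99.95% of held-out reads map back, and all 30
core genes are complete. `demo/out/` holds the QC accounting table,
metrics TSV, merged and robust FASTA, per-contig provenance and the run
log; re-running with the same seed reproduces them byte-identically.

A thin CLI over the same functions ships in
`inst/scripts/txconsensus` (subcommands `simulate`, `qc`, `subsample`,
`stats`, `dedupe`, `rmbt`, `completeness`, `merge`, `run`).

## Acceptance script

`scripts/acceptance.R` regenerates the standard simulated fixture
(500 transcripts, 50,000 read pairs) from the given seed, runs the entire
pipeline on it, and writes the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

S4 containers (`PairedReads`, `Assembly`, `MergedAssembly`,
`MappingResult`) wrap Biostrings objects with accessors (`mate1`,
`contigs`, `provenance`, `nTools`, ...). The methods vignette
(`vignettes/consensus-assembly.Rmd`) documents the model, parameter
choices, numerical decisions and limitations.
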