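# bacgrn

Systems-level analysis of a bacterial stress response when no regulon
annotation exists. Given a genome, a proteome, a reference database of
known prokaryotic transcription factors (TFs) with binding motifs, and a
time-series RNA-seq experiment, `bacgrn`:

- identifies the strain's TFs by exact local protein alignment
  (Smith–Waterman, BLOSUM62 11/1) with a Karlin–Altschul e-value screen
  (`E = K m n e^{-lambda S}`, threshold `E < 0.05`);
- transfers each TF's position weight matrix (PWM) from its closest
  reference TF and scans the genome on both strands with log-odds scores,
  keeping windows at ≥ 80% of the maximal attainable score;
- assigns every binding site to its closest gene (≤ 1 kb) and assembles
  the bipartite TF → target gene regulatory network (GRN);
- calls differentially expressed genes per timepoint (`|log2FC| ≥ 1` vs
  control), propagates each TF's signal over the GRN (restart walk,
  r = 0.5), scores TF influence as the correlation of propagated mass
  with `|log2FC|` over the DEGs, and greedily selects the **major TFs**
  of each timepoint by marginal DEG coverage;
- detects **operons** from coverage continuity with a 6-detector vote
  (≥ 3 votes per adjacent same-strand pair), summarizes each operon's
  dynamics as the operon value `O_{i,t}` — the mean member z-score at
  timepoint t — and clusters the profiles with k-means (k = 6);
- tests gene sets for pathway enrichment with the hypergeometric upper
  tail (significant at raw p < 0.05).

A bundled synthetic-data generator builds a complete toy study — a ~360 kb
genome with 300 genes, 40 operons, 10 planted TFs wired as a two-layer
master-regulator cascade, promoter binding sites, and a control + 5 min /
1 h / 3 h / 12 h count and coverage time course — with full ground truth,
so the entire pipeline is testable end to end without any downloads.

## Worked example

The analysis is organized as numbered drivers over the package:

```sh
Rscript analysis/01_simulate.R   # synthetic study + ground truth
Rscript analysis/02_degs.R       # fold changes, DEG calls, clustering
Rscript analysis/03_grn.R        # TF screen, motif scan, network
Rscript analysis/04_modules.R    # per-timepoint major TFs
Rscript analysis/05_operons.R    # operon calls, values, k-means
Rscript analysis/06_enrich.R     # pathway enrichment
```

With the default seed the drivers print:

```
Simulated 300 genes on 360372 bp; planted 10 TFs, 71 regulatory edges, 40 operons.

DEG counts by timepoint (|log2FC| >= 1):
       down up
  5min   14 18
  1h      6  8
  3h      4  0
  12h     5  2

Screened 10 TFs; 71 binding sites -> 71 unique edges.
Edge recovery vs planted truth: precision 1.000, recall 1.000

5min : 3 major TF(s) [g0014, g0051, g0073], 30 covered targets
Master regulator g0014 is selected at 5min.

113/206 candidate pairs voted operonic -> 40 operons; 51% of genes in operons.

115 tests, 6 significant at p < 0.05.
        query      pathway  k  K        p
    degs_5min path_regulon 16 31 1.01e-14
```

Reading this: the early (5 min) response is the largest and decays, as
planted; all 71 planted TF→target edges are recovered with no false
edges; the planted master regulator (`g0014`) has the top influence score
at the earliest timepoint and is selected into the 5 min module together
with the intermediate TF of the cascade (`g0051`); all 40 planted operons
are recovered from coverage; and the master's regulon shows up as the
overwhelmingly most significant pathway among early up-regulated genes.
Small tables land in `results/`, large per-sample coverage tracks in
`scratch/pipeline/`. The same stages are callable in R via
`run_pipeline("all", pipeline_config(outdir, seed))`, and each module is
an exported function (`smith_waterman()`, `scan_genome()`,
`select_major_tfs()`, `detect_operon_pairs()`, ...).

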