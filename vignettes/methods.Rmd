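---
title: "Homology-based GRN inference and time-series network analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based GRN inference and time-series network analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Radiation-resistant bacteria survive UVC by mounting a fast transcriptional
response — DNA-repair and ROS-scavenging programs switched on within
minutes and decaying over hours. For a non-model strain there is no curated
regulon database, so the regulatory structure behind that response has to
be inferred from sequence alone. `bacgrn` implements that inference as a
reusable, fully testable pipeline:

1. **TF identification by homology.** Strain proteins are aligned against
   a reference database of known prokaryotic TFs with exact local
   alignment (Smith–Waterman, BLOSUM62, affine gaps 11/1). A protein is
   accepted as a TF when its best hit has e-value below 0.05, computed
   with the Karlin–Altschul formula `E = K m n exp(-lambda S)` using the
   standard gapped constants (lambda = 0.267, K = 0.041) and the whole
   database's residue count as `n`.
2. **Binding-site transfer and scanning.** Each accepted TF inherits the
   position weight matrix (PWM) of its most similar reference TF. The
   genome is scanned exhaustively on both strands with background-corrected
   log-odds scores; windows reaching 80% of the maximal attainable score
   are reported as binding sites.
3. **Target assignment.** Each site is assigned to the closest gene
   (interval distance, overlap = 0) within 1 kb; ties resolve to the gene
   downstream of the site on the site's strand. The unique (TF, target)
   pairs form a bipartite gene regulatory network (GRN).
4. **Time-varying modules.** DEGs are called per timepoint by
   `|log2FC| >= 1` against the untreated control. Each TF's unit seed is
   propagated over the GRN (`p <- (1-r) W p + r p0`, restart r = 0.5,
   L1 tolerance 1e-6); its influence is the Pearson correlation between
   the propagated vector and `|log2FC|` over that timepoint's DEGs. TFs
   are then selected greedily in influence order, each keeping its place
   only if it covers at least one still-uncovered DEG target, until every
   coverable DEG is covered — an influence-maximization summary of who
   drives the response when.
5. **Operons.** Adjacent same-strand gene pairs are voted on by six
   deterministic detectors over RNA-seq coverage and expression (below);
   pairs with at least 3 of 6 votes chain transitively into operons. The
   operon value at time t is the mean of member z-scores at t; the
   time-ordered profiles are grouped with k-means into six perturbation
   patterns.
6. **Enrichment.** Gene sets (DEGs split by direction, module targets,
   operon clusters) are tested against a pathway database with the
   hypergeometric upper tail; significance is raw p < 0.05, with BH
   q-values reported alongside but not used for the flag.

# The synthetic study and its ground truth

The generator (`simulate_experiment()`) builds the study the analysis is
designed for, with full planted truth, so every stage is checkable without
downloads:

- **Genome.** One linear contig (~360 kb at defaults): 300 non-overlapping
  genes of 300–1500 bp; 40 operon blocks of 2–5 adjacent same-strand genes
  with intra-block gaps of at most 50 bp; all other gaps 300–600 bp, which
  doubles as the 300 bp promoter window.
- **TF database.** 20 reference TFs: random proteins of 100–300 aa paired
  with informative PWMs (8–14 bp, dominant base probability 0.85–0.97 per
  column; every column sums to 1).
- **Proteome.** One protein per gene. Ten standalone genes carry
  point-mutated copies (5% substitution rate) of ten distinct reference
  TFs; all other proteins are random. Protein sequences are sampled from
  the Robinson–Robinson background composition — the composition the
  BLOSUM62 Karlin–Altschul constants are calibrated for; a uniform
  20-letter alphabet would over-represent rare high-scoring residues
  (W, C) and inflate the random score tail.
- **Regulatory cascade.** The first planted TF is the master regulator: it
  directly controls 15 regulon genes plus an intermediate TF, which
  controls 15 more. The remaining TFs get small (5-gene) unresponsive
  regulons. Effects are split up/down within each layer. One
  consensus-sampled site per edge is embedded 5–100 bp upstream of the
  target's start, strand-aware.
- **Signal attenuation.** Indirect (intermediate-driven) targets respond
  at 0.7x the master's log2 effect. This mirrors signal decay along real
  cascades and keeps the influence statistic well-posed: with a uniform
  effect size the Pearson correlation over DEGs degenerates to a constant
  vector (score 0 by the degeneracy rule), and no TF could be ranked.
- **Expression.** Counts are negative binomial (dispersion 0.1) around
  baselines drawn log-uniformly from 120–1200; regulon means shift by
  `master_effect_log2 * effect_decay[t]` (2.0 x 1, 0.5, 0.2, 0.1 across
  5 min, 1 h, 3 h, 12 h), so the planted DEG sets shrink monotonically:
  strong early response, boundary response at 1 h, none later. Library
  sizes are equalized by construction, so fold changes need only a
  pseudocount (1 on the mean) and no between-sample normalization; a CPM
  option is not needed for the synthetic study and is out of scope here.
- **Coverage.** Per-base Poisson depth proportional to each gene's
  expression mean (factor 1/20), continuous across operon members *and*
  their gaps (co-transcription), with a 0.1 background elsewhere. Operon
  members share one baseline.
- **Site scrubbing.** After planting, any window outside the planted
  intervals that reaches the default scan threshold against *any*
  reference PWM is point-mutated until none remain (at most 25 sweeps).
  This makes the ground truth exact — the planted sites are the only
  sites — so edge precision/recall measure the method, not chance k-mer
  collisions in random DNA.
- **Pathways.** A "regulon pathway" collecting the master's full regulon,
  plus 12 random pathways; the background universe is the union of all
  pathway genes (an annotated-universe background, as one would use with
  a partially annotated strain).

The generator's TF-candidate list (`tf_candidates.txt`, the truth TF set)
stands in for the output of a TF-prediction step that precedes the
homology screen, and the default pipeline feeds it to `screen_tfs()`'s
`candidates` argument. This matters quantitatively: a *calibrated* e-value
threshold of 0.05 passes about 5% of random non-TF queries by
construction (we measure 4.7% on the toy database), and every false TF
inherits a real donor PWM and therefore duplicates that donor's regulon
edges. Screening the whole proteome without a prediction step is still
supported (`use_candidates = FALSE`) and all its contracts are tested,
but it cannot — for any realistic proteome size — keep edge precision
near 1; that is precisely why a dedicated TF predictor belongs in front
of the screen.

## What the generator does not emulate

Read-level artifacts (no FASTQ/SAM, no sequencing-error or mappability
model), multi-contig or circular genomes, operon-internal promoters,
condition-dependent operon boundaries, TF binding-site turnover (sites are
exact consensus), library-size imbalance, and batch effects. Passing the
planted-truth tests therefore shows the machinery is correct under the
stated model, not that the thresholds are optimal for any particular real
dataset.

# The six operon detectors

operon-pair voting uses six deterministic detectors over the
sample-averaged coverage; a candidate pair (adjacent, same strand) is
operonic with >= 3 votes:

1. intergenic gap <= 100 bp;
2. Kruskal–Wallis H over per-base coverage of {gene1, gap, gene2} below
   the chi-square(2) critical value at alpha = 0.05 (homogeneity);
3. mean gap coverage >= 0.5 x the smaller gene mean;
4. Pearson correlation of the two genes' timepoint-mean expression
   profiles >= 0.8;
5. minimum 25 bp sliding-window mean of gap coverage >= 0.3 x the smaller
   gene mean (no trough);
6. gene coverage means within 4-fold and both above a floor of 5.

A zero-length gap delegates the gap detectors to the two boundary bases;
a perfectly flat pair is homogeneous by definition (the Kruskal–Wallis
statistic is undefined under total ties). These are rule-based stand-ins
for a trained ensemble over the same signal families (distance, coverage
homogeneity, boundary continuity, co-expression), keeping the >= 3-vote
ensemble semantics while remaining free of trained weights; every
threshold is exposed in `operon_config()`.

# Numerical and design choices

- **z-score axis.** Operon values use per-gene z-scores across the five
  timepoint *means* (axis `"time"`), which makes profiles comparable
  across expression levels; standardizing across samples first and
  averaging per timepoint is available via `expression_zscores(axis =
  "samples")`. Zero-variance genes get all-zero z-rows.
- **Fold-change zero handling.** Pseudocount 1 on replicate-mean counts
  keeps all log2FC finite; an all-zero gene has log2FC exactly 0. The DEG
  boundary is inclusive (`|log2FC| >= 1`).
- **Expression clustering.** Average linkage on Euclidean distances of
  z-scored profiles, dendrogram cut at height 3 — the conventional
  default for heatmap-style response grouping; the linkage and metric are
  deliberate choices recorded here, the cut height is a config parameter.
- **Scan threshold.** Fraction-of-maximum log-odds (default 0.8) is
  self-calibrating across motif lengths; an absolute-score cutoff would
  need re-tuning per PWM. Scores carry a 1e-9 slack against float
  accumulation so a planted consensus can never miss its own threshold.
  Ambiguous bases (N) score 0 (the background expectation) per position.
- **Closest-gene cap.** `max_distance = 1000` bp prevents a gene-dense
  toy genome from linking every stray site to something; `Inf` restores
  unbounded closest-gene assignment.
- **Propagation.** Column-normalized TF->target operator; dangling
  columns stay zero so their mass decays to the restart term. Restart
  0.5, L1 tolerance 1e-6, cap 1000 iterations (a warning, not an error,
  on hitting the cap). Restart 1 returns the seed exactly.
- **Influence degeneracies.** Constant propagated or constant |log2FC|
  vectors over the DEGs score 0 rather than NA, so unreachable TFs rank
  at the bottom deterministically; ties in influence break by TF id.
- **k-means.** k-means++ (D^2) seeding implemented in-package (base R's
  `kmeans()` has no ++ init), 10 restarts, best total within-SS, fixed
  seed; `k` equal to the number of profiles returns the identity
  clustering.
- **Enrichment.** Raw p < 0.05 drives the significance flag (matching a
  fixed-threshold criterion); BH q-values are reported for transparency.
  Query genes outside the background are dropped with a message.
- **Determinism.** One global pipeline seed fans out to per-stage seeds
  via a stage-name hash; every generator stage runs under
  `withr::with_seed`, so a fixed seed gives bit-identical artifacts.

# Problem sizes

Defaults were chosen so the whole study runs comfortably on a laptop
core: 300 genes / ~360 kb genome, 20 reference TFs, 15 samples, and the
full pipeline (`run_pipeline("all", ...)`) completes in about half a
minute; the acceptance checks (oracle comparisons on 10 kb scans, 100
alignment pairs, 50 coverage instances, 10 generator seeds) add a few
minutes. Unit tests use a reduced 60-gene configuration where the full
default is not needed.

# Known limitations

- Edges are unsigned: no activation/repression polarity, and influence
  uses |log2FC|, so mixed-sign regulons are found but not oriented.
- The homology screen transfers the donor's PWM unchanged; binding-site
  divergence between the strain and the reference is not modelled.
- Operon-aware target expansion (a site upstream of an operon regulating
  all members) is deliberately not performed by the GRN stage; the operon
  and GRN analyses are combined only descriptively.
- The e-value uses fixed gapped Karlin–Altschul constants, not
  database-calibrated ones; e-values are comparable within this pipeline
  but not identical to BLAST's.
- The greedy module selection maximizes coverage given the influence
  ranking; it is exact on coverage (it never stops while a coverable DEG
  is uncovered) but the ranking itself is a heuristic prioritization.
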