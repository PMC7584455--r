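---
title: "Methods: Ty retrotransposon landscapes from processed sequencing derivatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ty retrotransposon landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tylandscape` analyses the genomic landscapes of Ty LTR retrotransposons
in yeast lineages. Ty elements are ~5 kb internal sequences flanked by two
~300 bp long terminal repeats (LTRs) in direct orientation; intra-element
recombination between the two LTRs deletes the internal sequence and one
LTR, leaving a solo LTR. The package takes processed, standard-format
derivatives of sequencing experiments — defragmented element annotations,
pairwise LTR hit tables, whole-genome multiple-alignment blocks, per-locus
depth tables, SNP genotypes, insertion-call tables, climate records, tree
files and growth-plate readings — and implements the downstream
computations: similarity networks and family merging, divergence since
transposition, cross-genome orthogroups, read-depth copy numbers,
insertion allele spectra, structure/climate association models, selection
and diversity statistics, branching-time curves, and growth-assay
analysis. Upstream steps (read mapping, variant calling, repeat
annotation, alignment computation, phylogenetic inference, codon-model
fitting) are out of scope; their outputs are inputs here.

A synthetic-data generator produces truth-known versions of every input
so that each stage can be validated against a planted ground truth.

# The synthetic generator

`simulate_te_genomes()` evolves an ancestral backbone sequence along a
lineage tree under Jukes–Cantor-like substitution (per-site substitution
probability equal to the branch length in substitutions/site; no indels
outside element insertions). Its design choices, and what they do and do
not emulate:

* **Master-copy transposition.** A transposition event plants a
  full-length element whose sequence equals the family's ancestral
  consensus at the moment of insertion, flanked by a target-site
  duplication (default 5 bp, typical of Ty integration). LTR divergence
  therefore accumulates with time since insertion, which is exactly the
  signal the divergence estimator exploits. Real transposition copies an
  active donor element, so real divergences have an extra donor-age
  component the generator omits.
* **Solo-LTR formation** converts a full-length element to its 5' LTR at
  a per-branch-length rate. Ancestral (root) elements are already solo
  with probability 0.8, reflecting the empirical structure of these
  genomes: solo LTRs outnumber full-length elements roughly tenfold, and
  deeply conserved insertion loci carry few full-length members. Ancestral
  elements also receive an extra age (uniform up to 0.15
  substitutions/site) so that ancient solo LTRs span the tens-of-percent
  divergence range seen in real annotations; without it, all ages would
  sit within the binomial noise of a 330 bp LTR comparison.
* **No nested or tandem insertions.** Insertion anchors keep a minimum
  spacing (default 2 kb), so each insertion column band in the implied
  alignment contains exactly one orthogroup and 1-D clustering at
  eps = 500 cannot chain distinct loci. Real genomes do contain nested
  elements; resolving them is an annotation-defragmentation problem that
  is upstream of this package.
* **Alignment blocks** are emitted at megabase scale by default, because
  collinear yeast genomes produce chromosome-scale locally collinear
  blocks. The block structure is stored as per-genome ungapped segments,
  from which gap structure, informative-site fractions and coordinate
  projections are computed exactly; a minimal MAF writer/reader
  round-trips this representation.
* **Hybrids** are position-wise mosaics of two tip genomes with
  geometric block lengths (mean 50 kb) — lineage-level admixture, not a
  recombination-graph simulation.
* **Strand.** All planted elements are recorded on the forward strand;
  mixed-strand behaviour of the confident-orthogroup filter is exercised
  with constructed tables in the tests instead.
* **Depth tables.** Per-locus *median* depth is the median of per-base
  negative-binomial draws over the locus (5 kb internal references, 1 kb
  control genes), with variance `mu + dispersion * mu^2` per base and
  expectation `coverage * CN`. At dispersion 0 the depth equals its
  expectation exactly, giving the noise-free limit the depth module's
  invariants use. Genome-wide depth equals the configured coverage, i.e.
  copy number 1 per haploid genome equivalent.
* **Population structure** follows a Balding–Nichols model with
  differentiation 0.7 by default; these lineages are incipient species,
  and with this value the first genotype PC alone captures about half of
  the total variance, as observed in wild panels of this system. Hybrid
  lineages mix their parents' allele frequencies. Climate records are
  yearly series per location whose means either share a latent lineage
  factor (coupled) or are independent (decoupled).
* **Insertion calls.** Each true insertion emits 1 + Poisson(1) calls
  with Gaussian positional jitter (SD 100 bp); with probability 1 one of
  them carries the high-quality flag (8), matching the discovery
  behaviour that accepted clusters contain at least one flag-8 call.
  False positives (never flag 8) arrive at 0.005 calls per genome kb.
* **Growth plates** are logistic curves on a 15-minute grid with a
  lineage-specific multiplicative rate effect under stress and i.i.d.
  OD noise.

Because the generator is substitution-only, noise-free in coordinates and
free of nested elements, passing its tests demonstrates the correctness
of the downstream computations under the stated statistical structure; it
does not demonstrate robustness to mis-annotation, alignment error or
structural variation in real data.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| edge retention percentile | 10th (per query LTR) | bit score | network edge filter |
| clustering `eps` | 500 | alignment bp | 1-D DBSCAN with `min_samples = 1`, i.e. chaining |
| confident-orthogroup hit filter | >= 80% identity, 90–110% length | – | restricts the empirical coordinate-difference distribution to unambiguous orthologs |
| coordinate threshold | 95th percentile of pooled start/end differences | bp | orthology coordinate agreement (17 bp on the original assemblies) |
| NRD floor | 10th percentile of control-gene NRD | log2 units | resolves `-Inf` sentinels from sparse coverage; −1.25 on the original panel |
| divergence split | 1% | divergence | low/high divergence contrast classes |
| PC retention | 80% cumulative variance | – | gPC/ePC sets |
| affinity propagation | damping 0.8, max 10000 iterations, median-similarity preference | – | structure clustering |
| FDR | Benjamini–Hochberg, alpha 0.05 | – | all multiple-testing corrections |

All percentiles use linear interpolation (R's type-7 quantile), recorded
in `percentile()` so every threshold shares one method.

# Design decisions where the procedure was open

* **Best hits.** A pair of cluster members is linked when at least one
  direction's hit is the query's best hit *within the subject's genome*
  (the standard reciprocal-best-hit building block), not merely its best
  hit among all cluster members. The latter reading disconnects clean
  clusters whenever two sister-genome members are mutually closest, and
  would split genuine orthogroups; the per-subject-genome reading leaves
  the coordinate criterion as the operative filter. Mutual best hits are
  not required — one direction suffices.
* **Representative coordinate for clustering** is the annotation start
  in alignment coordinates (midpoint available via an argument).
* **Orthology closure.** Pairwise orthology is closed transitively
  within a cluster (connected components), yielding a partition; groups
  with more than one member in a genome are flagged `discarded` rather
  than deleted.
* **One LTR per full-length element** in divergence estimation: the 5'
  LTR, deterministically, for reproducibility. Intra-element hits are
  excluded before the best hit is taken. The per-query retention
  percentile is computed over all non-self hits, including hits that the
  intra-element exclusion later removes.
* **Clade selection intensity** averages over the crown branches of the
  smallest subtree spanning the tips (internal branches included, stem
  branch excluded); non-monophyletic tip sets are an error rather than a
  silent approximation.
* **Edge filter idempotence.** Retention thresholds are a function of
  the original hit table; re-applying those thresholds to the retained
  set is a no-op. Recomputing percentiles on an already-filtered table
  would progressively erode the network and is deliberately not done.
* **Pooled start/end differences.** Start and end coordinate
  differences are pooled into one distribution before taking the
  percentile.
* **Window trimming** proceeds inward from both block ends until a
  window meets the informative-site fraction; interior windows are never
  removed.
* **"Summing all timepoints"** for the growth AUC is the literal
  rectangle rule with unit step, not trapezoidal integration.
* **Replicate SD z-scoring** for growth homoscedasticity is global
  across strains, not per lineage.
* **Floor scope.** The −1.25-style floor derives from control genes and
  is exposed as an explicit function pair (`derive_floor()`,
  `apply_floor()`), so callers choose which strain sets to floor; the
  association module floors copy numbers before modelling.
* **Conover post-hoc tests** are reported for all pairs with
  Benjamini–Hochberg correction, not gated on the Kruskal–Wallis result.
* **Ultrametricity tolerance** is relative (1e-6 of the tree depth);
  the rooting outgroup is pruned before branching times are scaled.
* **Affinity propagation** is implemented in-package (standard
  responsibility/availability updates with damping) because no installed
  R implementation was available; its preference parameter defaults to
  the median similarity and convergence requires a stable exemplar set
  for 100 consecutive iterations.
* **Conover and Brown–Forsythe** are likewise implemented from their
  rank/median-deviation definitions; the Brown–Forsythe implementation is
  checked against the median-centered Levene test in an independent
  package in the test suite.

# Numerical choices and degenerate inputs

Zero depth maps to a `-Inf` NRD sentinel that must be floored before any
statistic. Constant responses short-circuit to p = 1 with a warning
(Kruskal–Wallis stage) or a tie flag (Mann–Whitney stages). All-zero
paired differences make the Wilcoxon stage degenerate; it reports p = 1
with a flag. Rank-deficient model matrices are errors naming the
collinear columns, never silent drops. Ties in best-hit selection break
by lower e-value, longer alignment, then lexicographic subject id, so
outputs are order-independent.

# Problem sizes

The package's validation benchmarks run on six 2 Mb genomes with three
families and ~60 planted orthogroups; 100 strains for copy-number
recovery; 204 strains × 1000 SNPs × 200 replicates for the association
comparison; 1000 null replicates per calibration test; and 30 replicates
of a 12-lineage growth design. These sizes give stable estimates while
keeping a full run in the minutes range on one CPU.

# Known limitations

Real annotation pipelines produce truncated and orphan-internal
elements, nested insertions and strand mixtures that the generator does
not emit (the element types are supported in the data model and the
filters are tested on constructed cases). The divergence estimator
saturates for ancient elements; correlations with age are therefore
reported on unsaturated elements. Insertion calling covers non-reference
alleles only, as in the underlying discovery method. The association
framework assumes linear effects of the retained PCs; the
cluster-inconsistency contrast is a complementary non-parametric check.
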