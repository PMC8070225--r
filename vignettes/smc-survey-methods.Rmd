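---
title: "Methods: cluster typing, MCL families, synteny networks and the Alien Index"
author: "SMCsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster typing, MCL families, synteny networks and the Alien Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SMCsurvey)
```

This vignette is the package's account of its methods: what each stage
computes, which parameters matter and why they default to what they do,
what the synthetic-data generator does and does not emulate, and where a
genuinely open design choice was settled.

## Data model and coordinates

A candidate secondary metabolite cluster (SMC) is a `ClusterRegion`: an
interval on one contig of one assembly with an ordered list of gene models
(protein-coding, with translations). All internal coordinates are 0-based
half-open; GenBank's 1-based inclusive convention is converted exactly at
the file boundary, which keeps every distance computation (synteny gaps in
particular) free of off-by-one ambiguity. Compound (`join`) locations are
collapsed to their outer span: the analysis operates at gene granularity
and never looks inside exon structure. How upstream prediction tools
handle overlapping or trans-spliced gene models is not standardised, so
the outer-span collapse is a deliberate simplification; regions produced
by any exporter that writes one CDS per gene round-trip exactly.

Domain accessions are normalised on input (version suffixes stripped,
CDD's `pfamNNNNN` spelling mapped to `PFNNNNN`) so that rule matching is
database-version independent.

## Rule-based typing

`assignType()` evaluates a rule table against the *set* of domain
accessions seen on a cluster's proteins. A rule is a conjunction of
any-of alternative sets plus an exclusion set; the highest-priority
satisfied rule gives the primary type and every other satisfied rule a
hybrid label. The defaults (`defaultRuleTable()`) encode the canonical
biosynthetic signatures; three entries deserve comment:

* **Siderophore** requires only IucA_IucC (PF04183). NRPS-independent
  siderophore regions frequently consist of a single IucA/IucC homologue;
  demanding the corroborating FhuF domain (PF06276) would silently drop
  many genuine regions.
* **Polyprenyl synthetase** is PF00348. The literature occasionally prints
  the five-digit string "PF003480", which is not a valid Pfam accession;
  PF00348 is the only plausible referent.
* **PKS** uses the ketoacyl-synthase N/C signatures (PF00109 | PF02801),
  and condensation/thioesterase are fixed to PF00668/PF00975. Upstream
  classifiers keep their full rule grammars internal, so this table is an
  explicit, auditable reconstruction — every accession is visible and
  overridable, and additional types (betalactone, fungal-RiPP, ectoine)
  can be supplied as user rules; no built-in signature ships for them
  because none is established.

Priorities default to NRPS > PKS > siderophore > terpene > NRPS-like >
bacteriocin, i.e. information-richer signatures win and the weaker
adenylate-only signature never masks a full NRPS; the order is data, not
code, and can be changed. `curateAssignments()` then rejects clusters with
no satisfied rule — distinguishing fatty-acid-synthesis-like false
positives (4'-phosphopantetheinyl transferase, PF01648, as the *only*
signature) from signature-free candidates — so every rejected cluster
carries a machine-readable reason.

Assignment is a pure function of the domain set: gene order, hit order and
duplicate hits are irrelevant, and adding a domain can only add satisfied
rules (with the one documented exception of the NRPS-like exclusion set).

## Protein families: MCL from scratch

The similarity graph admits a protein-vs-protein hit iff its E-value is at
most the threshold (default `1e-10`) and weights the edge
`min(200, -log10 max(E, 1e-200))`. The log transform is standard practice
for E-value-derived weights; the cap handles reported E-values of 0 and
bounds the dynamic range so one saturated edge cannot dominate the flow.

`mclCluster()` implements the Markov Cluster Algorithm directly: add
self-loops (per node, the maximum incident weight, or 1 for isolated
nodes), column-normalise, then iterate expansion (matrix squaring),
inflation (entrywise power, default 1.55, then column renormalisation)
and pruning of entries below `1e-5`, until the largest entry change falls
below `1e-6` or 100 iterations. Column sums are restored to 1 after every
inflation and pruning step, so the matrix stays stochastic throughout.
Clusters are read off attractor rows; because MCL can in principle emit
overlapping attractor systems while the downstream analysis assumes a
partition, each node is assigned to the attractor holding the largest
value in its column (ties to the smallest attractor index), and assignment
chains are followed to their root. The procedure contains no randomness;
identical inputs give identical families. Families are ranked by
decreasing size, ties broken lexicographically by smallest member id, so
`MCL0001` is reproducibly the largest family.

The implementation uses dense base-R matrices: SMC-encoded protein sets
are a few hundred to a few thousand proteins, where dense expansion is
simple and fast enough. It deliberately does not reproduce the reference
MCL implementation's sparse-matrix machinery; `writeAbcGraph()` exports
the graph for that tool when datasets outgrow the dense path.

**Parameter sampling.** The admission threshold and inflation are the two
parameters that matter, and both are chosen by exhaustive grid evaluation
(`silhouetteSample()`) under the mean silhouette width
`s(i) = (b(i) - a(i)) / max(a(i), b(i))` with the graph-derived distance
`d(a, b) = 1 - w(a, b)/200` (1 for non-adjacent pairs). Points in
singleton families are excluded, and a sample is flagged undefined unless
at least two families of size >= 2 exist, since silhouette is meaningless
at one cluster. The distance definition and the grid ranges are this
package's documented defaults for the procedure, not a claim about how
any particular study sampled; both are exposed.

## The synteny-aware similarity network

Cluster-pair scoring follows the multi-gene homology-search tradition with
two behavioural switches:

* **Coverage** is computed as alignment span normalised to the *query*
  length, and the 60% threshold is applied to both query and subject side
  by default. A bare "minimum sequence coverage" threshold does not name a
  side; bilateral is the stricter, symmetric reading, and
  `coverage_mode = "query"` provides the unilateral one.
* **Single matches.** Legacy behaviour demands at least two syntenic hits
  per cluster pair; the default here is `min_hits = 1`, because
  single-gene regions — siderophore synthases above all — otherwise
  cannot connect to anything.

Filtered hits between a cluster pair are grouped into syntenic regions by
a single scan in query-gene order: a hit joins the current group iff the
gap between the group's running span and the hit's gene interval is at
most 1 Mbp on *both* genomes (the boundary itself joins: the test is
`<=`). The best group (most hits, ties by summed bitscore) is scored

```
score = n_hit_genes + synteny_weight * synteny_score
```

with `n_hit_genes` the distinct query genes hit and `synteny_score` the
longest chain of hit pairs colinear in gene order on both clusters; a
chain may run in reversed subject order, so inverted but contiguous
segments still score. `synteny_weight` defaults to 0.5, the original
tool's convention, and is configurable since modified derivatives do not
restate it. The edge weight is the mean percent identity over the best
group's hits — genes without hits do not contribute zeros, since
zero-padding is described nowhere and would make single-match weights
meaningless. One edge per cluster pair (the best group) matches how such
networks are drawn and analysed. Graph export is GraphML plus a TSV edge
list; layout is a presentation concern and out of scope.

These invariants are enforced by tests: edge symmetry under hit-table
transposition, the `min_hits = 1` superset property, per-edge threshold
compliance, monotonicity under a rising identity threshold, and
`synteny_score <= n_hit_genes <= n_hits`.

**Toy aligner.** `toyLocalAlign()` is a self-contained
Smith-Waterman-Gotoh local aligner (BLOSUM62, affine gaps costing
`gap_open + L * gap_extend`) so that tests and demos can produce homology
hits without an external search tool. Its E-value comes from a fixed
Karlin-Altschul approximation (`E = K m n exp(-lambda * raw)` with
lambda = 0.267, K = 0.041) and is documented as an approximation: it is
self-consistent, monotone in the score, and not a BLAST replacement.
Tests verify the optimal scores against an independent pre-installed
dynamic-programming implementation on exhaustive small instances.

## Alien Index

For each SMC-encoded gene, best hits are taken per taxon group — the
recipient lineage (Dikarya, the higher fungi) versus the candidate donor
group (Bacteria) — after discarding hits above the E-value ceiling
(default 1e-05) and self-matches. The statistic is

```
AI = ln(best_E_Dikarya + 1e-200) - ln(best_E_Bacteria + 1e-200)
```

so `AI > 0` means the bacterial hit is stronger and the gene is a
horizontal-transfer candidate. The natural-log base and the `1e-200`
pseudocount follow the established Alien Index formulation; a group with
no qualifying hit contributes a best E of 1 (the weakest possible hit),
which keeps AI finite and conservative. Cluster-level aggregation reports
`avg_AI` (mean over all genes; genes with no hits in either group
contribute 0 rather than being dropped, so sparsely annotated clusters
are not biased toward their annotated genes — this is configurable) and
`avg_AI_core` (mean over genes in the core families: the signature
biosynthetic families plus FAAL; undefined when a cluster has no core
gene). No numeric AI cut-off is applied anywhere: the package reports
values, not verdicts, because any threshold depends on database
composition and taxon sampling.

## What the synthetic data emulates — and what it does not

`generateDataset()` plants, under a single integer seed: cluster regions
instantiated from per-type domain templates (each template satisfies
exactly its own typing rule) on synthetic contigs with 0.2-2 kb
intergenic gaps and 2 Mb between consecutive clusters; protein families
at a controlled pairwise identity (random ancestor, independent uniform
point substitutions at rate `1 - sqrt(t)` per member so expected pairwise
identity is `t`); homologous cluster groups distributed across
assemblies; decoy domain hits at a per-gene rate of 0.1 drawn from a pool
disjoint from every rule accession; and per-gene taxonomic best-hit
exponents with a configurable asymmetry in orders of magnitude.

`generateHitTable()` converts planted family identity into homology hits
with full coverages and the monotone law
`E = 10^(-(identity/100) * length / 15)`, clipped to `[1e-180, 10]`. The
divisor 15 is calibrated so that the survey's `1e-10` admission threshold
separates well-conserved within-family pairs (80% identity) from diverged
between-family pairs (20%) across the whole default gene-length range of
200-600 residues: admission at 80% requires length > 187, exclusion at
20% holds up to length 750. A steeper constant would make the separation
property fail at the short end of realistic gene lengths.

The generator controls identity, not evolutionary realism: substitutions
are uniform over the amino-acid alphabet (no substitution-matrix
weighting), there are no indels, no gene structure, no phylogeny, and
coverage is always complete. Passing tests therefore demonstrate that the
algorithms recover planted signal under controlled conditions — exact
typing from domain content, exact family and group recovery when
identities straddle the thresholds, correct AI signs under a 20-order
asymmetry — not that the thresholds are optimal for real, noisy,
fragmented assemblies, where gene-model quality is known to dominate
detection.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a laptop-class single
core: 200 template clusters for typing fidelity; a 40-protein planted
partition and 100 random graphs of at most 12 nodes for the MCL and
silhouette oracles; 20 clusters in 5 homology groups for network
recovery; 200 clusters with planted bacterial cores for AI sign recovery;
50 alignment pairs of at most 20 residues against the exhaustive-DP
oracle. Convergence and tie-break constants (`prune_below = 1e-5`,
`tol = 1e-6`, `max_iter = 100`, lexicographic tie-breaks for family ranks
and attractor indices) are all exposed as arguments; every tie-break is
deterministic so that reruns are byte-identical, which the pipeline tests
assert at file level.

## Known limitations

* The GenBank parser handles the region-per-record, CDS-with-translation
  subset that cluster exporters emit — it is not a general GenBank
  implementation.
* Dense-matrix MCL scales to thousands of proteins, not millions; use the
  ABC export and the reference implementation beyond that.
* The toy aligner's E-values are approximate by construction; any
  quantitative homology analysis should ingest real search output.
* Taxonomic group labels are taken as given (`Dikarya`/`Bacteria`);
  resolving NCBI taxids to groups is upstream of this package.
* AdenylPred-style substrate predictions are ingested, never computed:
  the predictor is an external trained model.
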