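---
title: "Iterative embedding-based binning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative embedding-based binning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microbin)
```

## The problem

Metagenomic assembly yields contigs from many organisms mixed together.
Binning groups contigs by genome of origin using two signals: genomic
signature (k-mer frequencies, which are genome-characteristic around k = 4)
and depth of coverage (which tracks organism abundance, and differs between
organisms across samples). `microbin` implements an iterative engine: embed
the un-binned contigs in two dimensions, cluster the embedding by density,
keep clusters whose single-copy marker genes indicate a sufficiently
complete and pure genome, loosen the thresholds on a fixed schedule, and
repeat on the leftovers.

## Features

Each selected contig is described by canonical k-mer counts for k = 2, 3, 4
(a k-mer is pooled with its reverse complement under the lexicographically
smaller representative, because assembled contigs have no consistent
strand) concatenated with per-sample average depths. Both blocks are
centered log-ratio (CLR) transformed per row: counts and depths are
compositional, and CLR places them on a scale where Manhattan distances are
meaningful. CLR needs strictly positive entries, so a pseudocount of 1 is
added to k-mer counts and 1e-5 to depths; both are configurable. With a
single sample a per-row CLR of a one-element composition is identically
zero, so the depth column is instead log-transformed and centered by its
median across contigs — a documented deviation that preserves the
information a one-column CLR would destroy.

Regions whose k-mer statistics mislead — rRNA genes (highly conserved
across taxa) and CRISPR arrays (containing foreign spacers) — are masked
using the structural annotation: any k-window overlapping a masked interval
is simply not counted. The sequence itself is never edited, and bin FASTA
output always contains the untouched input contigs.

## Contig selection

Contigs shorter than 500 bp are dropped outright. The single-sample routine
further restricts each embedding to the union of (i) the N90 prefix — the
longest contigs jointly covering 90% of the assembly — and (ii) contigs at
or above a category minimum (2250 bp by default, for contigs with and
without marker genes). The union (rather than intersection) reading keeps
the maximum amount of information; only short, information-poor contigs are
excluded. The co-assembly routine skips size selection and embeds all
un-binned contigs of at least 500 bp, because multi-sample depth profiles
carry enough signal for short contigs too.

## Dimensionality reduction

Features are first reduced by PCA to the smallest number of components
explaining 75% of the variance, capped at 75. The 2-D embedding is exact
t-SNE with a multi-scale Gaussian input kernel at two perplexities,
Manhattan input metric, and a schedule driven by the number of un-binned
contigs (NUC):

* early exaggeration `EX = clamp(NUC * 2.5e-4, 4, 100)`. The printed
  form of this rule in the source literature nests its min/max the wrong
  way round (it would always evaluate to 4); the clamp reading matches the
  stated intent that exaggeration scales with dataset size, and is what we
  implement.
* learning rates `LR_EX = max(2, NUC / EX)` for the early phase and
  `LR = max(200, min(64000, NUC * 0.1))` for the main phase.
* perplexities start at (10, 100) and advance by (2, 5) per binning
  iteration, capped at (20, 130). When the pool is smaller than three times
  the large perplexity both values shrink proportionally so that the large
  one is `(n - 1) / 3` — small-n behaviour the schedule otherwise leaves
  undefined.
* both optimization phases run in blocks of 250 iterations and stop when
  the KL divergence decrease since the previous checkpoint falls below 1%
  of the current divergence (strictly), with per-phase caps of 1000 and
  1500 iterations.

The t-SNE core is implemented exactly (O(n^2) gradients, in C++) rather
than with tree or interpolation approximations: per-iteration pools at the
scales this package targets (hundreds to a few thousand contigs) make the
exact gradient both fast and simpler to keep deterministic. The initial
layout is a seeded Gaussian with sd 1e-4; the same seed always reproduces
the same embedding.

## Clustering and assessment

The embedding is clustered with HDBSCAN (implemented in-package:
mutual-reachability minimum spanning tree, condensed tree at
`min_cluster_size = max(2, round(ln n))`, excess-of-mass selection, and the
cluster-selection-epsilon merge of micro-clusters). Our core distance
follows the reference implementation: the distance to the
`min_samples`-th nearest neighbour with the point itself excluded. Each
embedding is swept with `min_samples` = 1, 5, 10; contigs claimed by a MAG
in an earlier sweep are excluded from later sweeps. The epsilon cycles
0.25, 0.125, 0.0 per binning iteration.

Cluster quality comes from lineage-specific collocated single-copy marker
sets. Completeness is the mean over marker sets of the fraction of each
set's genes present; purity is the mean over marker sets of the mean
reciprocal copy number of the *present* genes. Absent genes are excluded
from the purity average — including them would re-penalize incompleteness
inside the purity score, which the completeness score already measures —
and a markerless group is vacuously pure (it can never pass the
completeness gate anyway). Assessment starts at the domain level, descends
one rank at a time (to class by default), reports sub-domain values
averaged with the domain value, and lets a deeper taxon take over when its
averaged completeness is equal or higher; ties break to the
lexicographically smallest taxon so runs are deterministic. A group with no
marker hits at all reports the first domain with completeness 0 instead of
descending through vacuous ties.

A cluster is accepted when its completeness meets the active threshold and
its purity meets the requirement: 95 while the completeness threshold is at
or above 90, else 92.5, escalating linearly to 95 as the cluster's own
completeness falls from 90 to 70 (to 99 when the assessment settled on a
domain-level set). The escalation's linear form is our choice; the source
only states that it increases continuously. Rejected clusters are
re-clustered in (embedding coordinates || raw depths) — the depth columns
rescaled to the coordinate spread so no high-coverage sample dominates —
with a split budget of 1 (2 in the final stage).

Contigs carrying at least 40 distinct markers are assessed alone before any
embedding; at purity >= 90% and completeness >= 92.5% they become
single-contig MAGs, since a complete genome on one contig would otherwise
risk dissolving into noise or merging with similar fragmented genomes.

## The iterative schedule

Single-sample: the completeness threshold walks 92.5 → 82.5 → 72.5. Within
a threshold step, the minimum contig size drops by 500 bp (to a floor of
500) whenever fewer than half the sweep runs yielded a MAG; when the size
floor is reached the threshold decrements and the size resets. At the
threshold floor the final recovery stage begins: purity relaxes to 87.5 for
clusters at completeness >= 90 and the split budget doubles; the run ends
when a final-stage iteration accepts nothing. Co-assembly: the threshold
drops by 10 every iteration to a floor of 70, iterations continue while
they keep producing MAGs, and the run finishes with terminal rounds
restricted to contigs of at least 2000, 1500, 1000 and 500 bp. Both
schedules are finite, so termination is guaranteed; the per-iteration log
records pool size, schedule state and acceptances, and every MAG carries
the thresholds that were active when it was accepted.

The epsilon cycle advances per embedding iteration (not per threshold
step), and one binning iteration is one (embedding, epsilon, sweep) pass —
the sweep runs are the "clustering steps" counted by the size-decrement
rule. Master seed `s` gives iteration `i` the embedding seed `s + i`, so
any single iteration can be replayed.

## The synthetic community generator

Test fixtures are generated, never downloaded. Each genome is an order-2
Markov chain whose 16 x 4 transition rows are drawn from a Dirichlet
(concentration 1); order 2 makes tetranucleotide signatures carry genome
identity, mirroring the biology of real genomic signatures without real
genomes. Genomes (0.8-1.5 Mb by default — smaller than typical bacterial
chromosomes, chosen so fixtures run quickly while leaving > 1000 contigs at
the default fragmentation) are cut at uniform random breakpoints into
50-300 contigs, given per-sample depths (lognormal genome abundances,
median ~30x, sdlog 1, times mild per-contig lognormal noise, sdlog 0.1),
and annotated: the genome's taxon marker complement from the bundled
miniature hierarchy planted exactly once with contigs weighted by length,
rRNA/CRISPR mask features on 5% of contigs, and 20 tRNA isotypes per
genome. A gold standard maps every contig to its genome.

Differential-coverage fixtures set `composition_groups` so two genomes
share one composition chain and use explicit anti-correlated abundance
profiles across samples — the classic multi-sample binning scenario where
only depth separates the genomes. The bundled marker hierarchy
(2 domains / 4 phyla / 6 classes, with synthetic accessions) is labelled
synthetic and stands in for a full lineage database at test scale.

What the generator does *not* model — sequencing error, strain-level
microdiversity, chimeric contigs, uneven within-genome coverage (GC bias,
replication origins), mobile elements shared across genomes — means
passing tests demonstrate the engine's correctness and its behaviour under
clean composition/coverage signals, not performance on real assemblies.

## Evaluation

Against a gold standard, a bin's reference is the genome contributing the
most base pairs (ties to the lexicographically smaller id); bp purity and
bp completeness follow the standard benchmarking definitions, and overall
purity divides the summed majority bp by the total binned bp while overall
completeness divides by the total gold-standard bp. The adjusted Rand index
is computed over binned contigs only (un-binned contigs are excluded — the
upstream benchmarking convention does not restate its choice, and this
reading keeps the index about binning decisions actually made). Tier calls
use marker-based quality with strict inequalities: HQ (purity > 90,
completeness > 70), NC (> 95, > 90), and MIMAG high-quality draft (NC plus
>= 18 tRNA isotypes and all of 5S/16S/23S).

## Numerical choices and degenerate inputs

* `ln` is the natural logarithm throughout; `ln(n)` cluster sizes round
  half-up with a floor of 2.
* Zero distances in the mutual-reachability graph (duplicate points) are
  lifted to 1e-12 before taking reciprocals for the condensed tree.
* GFF coordinates are 1-based inclusive everywhere; intervals are clipped
  to contig bounds and overlap-merged on parse.
* Contigs missing from the depth table get zero depth with a warning
  (zero-coverage contigs exist in real assemblies); negative or
  non-numeric depths are errors.
* An assembly where nothing passes selection returns zero MAGs with a
  warning; pools too small to embed advance the schedule instead of
  erroring.
* Bin ids are `bin_<iteration>_<ordinal>` with ordinals by descending
  total bp, so repeated runs produce identical names (iteration 0 is the
  single-contig rescue).

## Problem sizes used by the test suite

The standard end-to-end fixture is 10 genomes, 3 samples, 50-300 contigs
per genome (~1700 contigs, ~12 Mb); the differential-coverage fixture is 2
genomes sharing one chain at ~150 contigs. Module tests use communities of
2-5 genomes and a few hundred kb. These sizes exercise every code path —
rescue, sweeps, splitting, both schedules, terminal rounds — while keeping
a full run in minutes on one core; the engine itself has no hard-coded
size assumptions beyond the O(n^2) embedding and clustering cost.

## Known limitations

* Exact t-SNE and dense HDBSCAN are quadratic in pool size; pools beyond
  ~20k contigs would need approximate backends.
* Marker assessment is only as good as the hierarchy provided; with the
  bundled synthetic hierarchy, taxon labels are fixture labels, not
  taxonomy.
* Embeddings are recomputed from scratch each iteration and never reused.
* Soft cluster membership, cluster merging across iterations, and
  refinement against other binners are out of scope.
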