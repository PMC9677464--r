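# microbin

Iterative embedding-based metagenomic binning with marker-set quality
assessment, in R.

Metagenomic assemblies mix contigs from many organisms. `microbin` groups
them into metagenome-assembled genomes (MAGs) by combining the two classic
binning signals — genomic signature (k-mer frequencies) and depth of
coverage across samples — in an iterative engine:

1. **Features.** Selected contigs are described by canonical k-mer counts
   (k = 2, 3, 4) concatenated with per-sample average depths, both
   centered log-ratio (CLR) transformed. rRNA genes and CRISPR arrays are
   masked out of the k-mer counts (their signatures mislead), without ever
   editing the sequence.
2. **Embedding.** PCA (75% variance, ≤ 75 components) followed by exact
   t-SNE with a multi-scale kernel (perplexities starting at 10 and 100),
   Manhattan input metric, and a schedule driven by the number of
   un-binned contigs *NUC*: early exaggeration
   `EX = clamp(NUC · 2.5e-4, 4, 100)`, learning rates
   `LR_EX = max(2, NUC/EX)` and `LR = max(200, min(64000, NUC · 0.1))`,
   stopping when the KL divergence plateaus
   (`KLD_DIFF < KLD · 0.01`, checked every 250 iterations).
3. **Clustering.** HDBSCAN on the 2-D embedding
   (`min_cluster_size = max(2, round(ln n))`, a `min_samples` sweep of
   1, 5, 10, selection epsilon cycling 0.25/0.125/0).
4. **Assessment.** Clusters are scored against lineage-specific collocated
   single-copy marker sets: completeness is the mean fraction of each
   set's genes present (Parks-style); purity is the mean reciprocal copy
   number of the present genes,

   P<sub>MSS</sub> = (1/|MSS|) Σ<sub>MS</sub> (1/|MS<sub>present</sub>|) Σ<sub>g</sub> 1/C<sub>g</sub>.

   Acceptance requires completeness above a threshold that walks
   92.5 → 82.5 → 72.5 (70 for co-assemblies) and purity ≥ 95/92.5,
   escalating as cluster completeness falls. Contaminated clusters are
   split on raw depth; single-contig genomes (≥ 40 distinct markers,
   ≥ 90% pure, ≥ 92.5% complete) are rescued before any embedding.

A seeded synthetic-community generator (order-2 Markov genomes, lognormal
abundances, planted markers and annotations, gold standard) and an
evaluation module (bp purity/completeness, adjusted Rand index,
HQ/NC/MIMAG tiers) make the whole engine testable offline.

## Worked example

```r
library(microbin)

spec <- community_spec(n_genomes = 5, n_samples = 3,
                       contigs_per_genome = c(30, 60),
                       genome_length_range = c(2e5, 4e5), seed = 11)
bundle <- generate_community(spec)
hierarchy <- load_marker_hierarchy(mini_marker_db())

res <- run_binny(bundle$assembly, bundle$masks, bundle$hit_table,
                 bundle$depths, hierarchy, binny_config(seed = 0))
length(res$mags)
#> [1] 5
res$mags[[1]]$quality
#> quality_estimate: c__SynBacilli (class) completeness 1.000 purity 1.000 (20 markers)

lens <- setNames(Biostrings::width(bundle$assembly), names(bundle$assembly))
bins <- setNames(lapply(res$mags, `[[`, "contig_ids"),
                 vapply(res$mags, `[[`, "", "bin_id"))
score_bins(bins, bundle$gold, lens)[, c("bin_id", "reference",
                                        "bp_purity", "bp_completeness")]
#>    bin_id reference bp_purity bp_completeness
#> 1 bin_1_4  genome_1         1       0.9934341
#> 2 bin_1_2  genome_2         1       0.9974004
#> 3 bin_1_1  genome_3         1       0.9976386
#> 4 bin_1_5  genome_4         1       0.9980965
#> 5 bin_1_3  genome_5         1       0.9939262
overall_metrics(bins, bundle$gold, lens)
#>       purity completeness
#>    1.0000000    0.9961858
```

All five planted genomes come back as bins at bp purity 1.0; the missing
~0.4% of completeness is the base pairs on contigs below the 500 bp
filter. The marker-based quality estimate (completeness/purity 1.000 at
class rank) is what the engine used to accept each cluster; the bp scores
are the gold-standard view of the same bins.

A command-line interface wrapping the same functions ships in
`inst/scripts/`:

```sh
Rscript inst/scripts/microbin simulate --genomes 10 --samples 3 \
    --contigs-per-genome 50:300 --seed 7 --out community/
Rscript inst/scripts/microbin run --assembly community/assembly.fasta \
    --gff community/annotations.gff --markers community/marker_hits.tsv \
    --depth community/depth.tsv --marker-db "$(Rscript -e 'cat(microbin::mini_marker_db())')" \
    --out bins/ --seed 0
Rscript inst/scripts/microbin evaluate --bins bins/contig_to_bin.tsv \
    --gold community/gold_standard.tsv --assembly community/assembly.fasta --out eval/
```

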