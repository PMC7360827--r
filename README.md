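# beandiv

Morphological diversity analysis of common bean (*Phaseolus vulgaris* L.)
germplasm collections.

Germplasm curators characterize bean accessions on a standard set of 29
morpho-agronomic descriptors — 13 quantitative traits (days to flowering,
plant height, pod length, hundred-seed weight, ...) and 16 qualitative
traits scored as integer level codes (growth habit, flower color, seed-coat
speckling, ...), organized by plant organ. `beandiv` implements the standard
analysis pipeline over such trait matrices for breeders and genebank
scientists:

- **Phenotypic diversity.** Each qualitative trait's diversity is the
  Shannon–Weaver index over its level frequencies,
  H′ = −Σᵢ pᵢ ln pᵢ (natural log). Each quantitative trait is first binned
  into 10 classes of width 0.5 s centered on the trait mean X̄: class 1 is
  the open tail Xᵢ < X̄ − 2s, class 10 is Xᵢ > X̄ + 2s, and the interior
  boundaries are bₖ = X̄ − 2s + (k − 1)·0.5 s; H′ is then computed over the
  class counts, alongside the coefficient of variation CV = s / X̄. Trait
  indices aggregate to organ-level and collection-level arithmetic means,
  optionally split by the collection's ecological regions.
- **Clustering.** The full trait matrix (qualitative codes treated as
  numeric) is column-wise z-scored, Euclidean distances are computed, and
  accessions are clustered by UPGMA (unweighted pair-group average
  linkage); the dendrogram is cut into k groups and each group is profiled
  (trait means/s.d., modal levels).
- **Ordination.** Correlation-matrix PCA with the genebank reporting
  convention: component j's contribution rate is λⱼ / p × 100 % (p = number
  of traits), plus accession score scatters.
- **Gene-pool assignment.** Rule-based calls of cluster groups (or single
  accessions) to the Andean gene pool (large speckled seeds,
  erect/determinate habit, pale flowers), the Mesoamerican gene pool (small
  speckle-free seeds, prostrate/indeterminate habit, plain coats), or the
  introgressed type when signals of both pools co-occur, with regional
  composition tables.
- **Synthetic collections.** A generator with two gene-pool archetypes and
  trait-wise introgression produces labeled collections, so the whole
  pipeline can be exercised against known ground truth.

Everything is tidyverse-native: collections are tibbles, results come with
`tidy()`, `glance()` and `autoplot()` methods, and stages chain with the
pipe.

## Worked example

```r
library(beandiv)

# a labeled 115-accession collection: 52 Andean, 40 Mesoamerican,
# 23 introgressed accessions across four ecological regions
lab <- simulate_collection(simulation_config(seed = 1))

diversity_report(lab$collection)
#> Diversity report: 29 traits, overall mean H' = 1.504
#>
#> # A tibble: 9 × 4
#>   organ     kind         n_traits     h
#>   <chr>     <chr>           <int> <dbl>
#> 1 phenology quantitative        2 2.07
#> 2 pod       quantitative        4 2.05
#> 3 seed      quantitative        4 1.87
#> 4 plant     quantitative        3 1.83
#> 5 flower    qualitative         2 1.56
#> 6 seed      qualitative         5 1.50
#> 7 pod       qualitative         4 1.12
#> 8 plant     qualitative         4 0.652
#> 9 leaf      qualitative         1 0.599

z      <- standardize(lab$collection)
dend   <- upgma(euclidean_distances(z))
groups <- cut_dendrogram(dend, 4)
classify_gene_pool(summarize_groups(lab$collection, groups))
#> # A tibble: 4 × 7
#>   group  size call         andean_score mesoamerican_score seed_size
#> 1 G1       66 Andean                  4                  0 large
#> 2 G2       46 Mesoamerican            0                  4 small
#> 3 G3        2 Introgressed            2                  1 medium
#> 4 G4        1 Andean                  3                  1 large

correlation_pca(z)
#> Correlation PCA: 29 traits, 115 accessions
#>                      PC1     PC2     PC3     PC4
#> eigenvalue        8.3450  1.6988  1.6561  1.4745
#> contribution (%) 28.7758  5.8579  5.7105  5.0845
#> cumulative (%)   28.7758 34.6337 40.3442 45.4288
```

Reading the output: the overall mean H′ of 1.504 says the simulated
collection is highly diverse on the standard descriptor set; quantitative
seed and pod traits carry the most diversity, the single leaf trait the
least. At k = 4 the two big groups are the pure pools — the largest group
fires all four Andean marker rules (score 4 : 0, large seeds), the second
all four Mesoamerican rules — while the two residual groups contain
introgressed accessions with mixed signals. The first four principal
components of the trait correlation matrix explain 45.4 % of total
variance, with PC1 (28.8 % = 8.345/29) dominated by the traits that
separate the pools.

`run_full_report()` chains all stages and writes the diversity CSV/JSON,
Newick dendrogram, group labels, PCA report and scores, gene-pool calls,
regional composition, and a run log into one directory.

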