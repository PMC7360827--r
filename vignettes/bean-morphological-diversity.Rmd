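---
title: "Morphological diversity analysis of common bean germplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological diversity analysis of common bean germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beandiv)
```

## The problem

Common bean domestication produced two major gene pools — Andean and
Mesoamerican — that remain morphologically distinguishable: Andean
material tends toward large, speckled seeds, erect or determinate plants
and pale flowers; Mesoamerican material toward small speckle-free seeds,
prostrate indeterminate plants and plain black/yellow/white seed coats.
Regional landrace collections typically contain both pools plus
introgressed material carrying trait combinations from each. Curators
characterize such collections on a standard descriptor set of 29
morpho-agronomic traits (13 quantitative with units, 16 qualitative scored
as integer level codes, grouped by plant organ) and then ask three
questions: how diverse is the collection, how does it structure into
groups, and which gene pool does each group descend from. `beandiv`
implements that pipeline end to end, with a synthetic collection generator
providing ground-truth-labeled data for verification.

## Diversity model

**Qualitative traits.** The diversity of a trait is the Shannon–Weaver
index over its observed level frequencies,

$$H' = -\sum_{i=1}^{n} p_i \ln p_i,$$

with the natural logarithm, where $p_i$ is the share of accessions in
level $i$ and $n$ the number of non-empty levels. $H'$ ranges from 0 (one
level) to $\ln n$ (uniform). The natural-log convention matters: published
two-level indices such as 0.646 for a 65.2 : 34.8 split are only
reproduced in nats.

**Quantitative traits.** Each trait is first discretized into 10 classes
of width $0.5\,s$ centered on the trait mean $\bar X$ ($s$ = sample
standard deviation, $n-1$ denominator): class 1 is the open lower tail
$X_i < \bar X - 2s$, class 10 the open upper tail $X_i > \bar X + 2s$, and
the interior boundaries are $b_k = \bar X - 2s + (k-1)\cdot 0.5\,s$ for
$k = 1..9$. $H'$ is computed over the class counts; the coefficient of
variation $CV = s/\bar X$ accompanies it. Three edge conventions are fixed
in code and tests:

- interior classes are half-open $[b_{j-1}, b_j)$; a value exactly equal
  to $\bar X + 2s$ belongs to class 9, because the published tail rules
  are strict inequalities on both sides;
- when $s = 0$ every value sits in class 6, the class whose lower bound is
  $\bar X$ in the limit, giving $H' = 0$;
- missing values are dropped per trait (with a recorded count), so one
  incomplete trait does not disturb the others.

**Aggregation.** Organ-level indices are the arithmetic means of the
member traits' $H'$, split by qualitative/quantitative kind; the
collection-level index is the mean over all 29 traits; per-region indices
repeat the whole computation on each region's accession subset. The
arithmetic mean is adopted as the aggregation rule because it reproduces
every published organ-level value from the corresponding published trait
values to ±0.001 (e.g. seed qualitative 1.400 from {1.836, 1.814, 1.283,
1.055, 1.012}); no other simple aggregate does. Display rounding is
half-up to 3 decimals, matching how such tables are printed; all internal
computation is full precision.

## Clustering and ordination

All 29 traits — qualitative codes included, as numbers — are column-wise
z-scored and accessions are clustered by UPGMA on Euclidean distances.
Treating ordinal level codes as numeric is statistically debatable (one-hot
or Gower distances are the textbook alternatives) but is the convention of
this characterization literature, and the package follows it; `standardize()`
accepts a trait subset if a user prefers quantitative-only clustering.
Conventions fixed in code:

- merge heights are the average inter-cluster distances themselves, not
  halved; after a merge, distances to the new cluster are size-weighted
  averages (the "unweighted pair-group" definition, in which every member
  pair counts equally);
- tie-breaking among equal-minimum merge pairs follows the underlying
  `stats::hclust` convention; ties have probability zero on continuous
  data, and all height-based results are tie-invariant;
- constant trait columns cannot be z-scored and become all-zero columns
  with a warning (they carry no distance information);
- rows with any missing included-trait value are dropped with a message —
  a Euclidean distance on partially missing rows would silently change
  meaning;
- cutting into $k$ groups removes the $k-1$ highest merges; group labels
  are assigned by decreasing size. The default $k = 4$ mirrors the group
  count conventionally reported for provincial bean collections.

PCA is performed on the trait **correlation** matrix (not covariance), so
total variance equals the number of traits $p$ and component $j$'s
contribution rate is $\lambda_j / p \times 100\%$ — the convention under
which published eigen-tables' contribution rows are recovered from their
eigenvalue rows (4.3895/29 = 15.14%). Scores are the z-scored data on the
eigenvectors, so the sample variance of score column $j$ equals
$\lambda_j$. Eigenvector signs are fixed by making each column's
largest-magnitude loading positive; this is arbitrary but deterministic,
which the tests require.

## Gene-pool rules

Cluster groups (via their profiles: quantitative means, qualitative modal
levels) or single accessions are scored against four Andean marker rules
(HSW ≥ 35 g; speckled seed coat; erect growth habit or determinate podding
habit; white-to-pink flower) and four Mesoamerican rules (HSW < 25 g;
speckle-free coat; prostrate and indeterminate habit; plain
black/yellow/white seed-coat color). A pure-pool call requires a margin of
at least two rules; closer scores are called Introgressed. The margin rule
operationalizes the qualitative judgment that introgressed groups "combine
characteristics of both pools": one stray marker should not flip a call,
and a genuinely mixed profile fires rules on both sides. Seed-size market
classes use the standard hundred-seed-weight thresholds small < 25 g ≤
medium ≤ 40 g < large, consistent with reported group means around 33–35 g
("medium") versus 40.4 g ("largest"). Missing profile fields simply fire no
rule (HSW itself is required); evidence lists the fired rule names for
auditability.

## Synthetic collections

The generator draws accessions from two pool archetypes shipped as a
human-editable YAML parameter file (`inst/extdata/pool_archetypes.yaml`):
per-trait Normal (mean, sd) for quantitative traits, truncated at zero by
resampling; categorical level probabilities for qualitative traits. The
seed length/width ratio LWS is derived as SL/SW from the realized draws
rather than sampled, preserving its definition. Introgressed accessions
are trait-wise mosaics: each trait independently comes from the Andean
parent with probability λ (default 0.5), else the Mesoamerican parent —
mirroring how introgressed germplasm shows some traits from each pool,
and keeping categorical traits well-defined (a parametric blend of level
codes would not be).

The default configuration emulates the composition of a 115-accession
provincial collection: 52 Andean, 40 Mesoamerican, 23 introgressed (20% of
the total), spread over four ecological regions with the Mesoamerican pool
relatively more frequent in region I and introgressed material more
frequent in regions III–IV. The archetype means are anchored to published
group profiles where those exist (Andean HSW ≈ 42 g vs Mesoamerican ≈ 22
g; maturity 71 vs 79 days; pods per plant 7.3 vs 10.3;
erect/determinate/speckled vs prostrate/indeterminate/speckle-free); all
dispersions and the remaining levels are invented, plausible defaults —
published characterizations report group summaries, not distributions, and
the parameter file says so rather than implying false precision.

What the simulation does **not** emulate: trait–trait correlation within a
pool (traits are drawn independently given the pool), measurement error
structure, year/site effects, rare off-type levels, or any genetic model
of introgression (λ applies per trait, not per linkage block). Pipeline
tests passing on synthetic data therefore demonstrate algorithmic
correctness and recoverability under the stated generative model — not
that any real collection will split as cleanly.

## Verification strategy and problem sizes

Every numerical rule is tested against an independent oracle rather than
against itself: class binning against a literal boundary-enumeration
binner on 200 random vectors (plus a frozen 12-value case and an exact
floating-point boundary case built from the multiset {−2, 0×7, 2}, whose
sample sd is exactly 1); UPGMA against a naive cubic re-implementation
that recomputes every average pairwise distance from scratch, on random
instances up to 12 leaves; PCA against closed forms (orthogonal columns →
all eigenvalues 1; two traits → 1 ± r) and the spectral reconstruction
identity. Recovery experiments use 50 seeded replicates of two 25-accession
pure pools: the k = 2 cluster cut must reach adjusted Rand index ≥ 0.9 in
at least 45 replicates, and the gene-pool classifier must recover the
generating pool for at least 90% of recovered groups. A separation sweep
(archetypes interpolated toward their midpoint at 5 settings, 8 replicates
each) checks that recovery degrades to chance as the pools merge. These
sizes keep the full suite around three minutes on one core while leaving
the statistical assertions comfortable margins.

## Known limitations

- Numeric coding of qualitative traits in distances and PCA inherits the
  field convention's weaknesses: level codes are treated as equally spaced.
- The diversity index has no uncertainty quantification (no
  bootstrap/rarefaction); published practice reports point values.
- Gene-pool rules are morphological heuristics; molecular markers
  (e.g. phaseolin) would be more decisive and are out of scope.
- Regional composition requires every accession to carry a region; the
  full-report runner skips that table (with a log entry) when no regions
  are present.
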