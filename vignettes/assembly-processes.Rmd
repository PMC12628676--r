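---
title: "Quantifying community assembly processes with phylogenetic and taxonomic null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community assembly processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeassembly)
```

## The question and the framework

Microbial communities are shaped by a mixture of deterministic processes
(selection imposed by the environment) and stochastic processes (dispersal
and ecological drift). `lakeassembly` quantifies their relative contributions
from two pairwise null models, applied to every unordered pair of samples
within a habitat:

1. **Phylogenetic turnover.** The between-community mean nearest-taxon
   distance (betaMNTD) measures how phylogenetically close each taxon in one
   community is to its nearest relative in the other, weighted by relative
   abundance. Its standardized effect size against a taxa-shuffle null, the
   beta nearest-taxon index (bNTI), diagnoses selection when niche optima
   carry phylogenetic signal: bNTI < -2 means the pair is more
   phylogenetically similar than chance (homogeneous selection), bNTI > +2
   less similar (variable selection). Both inequalities are strict.

2. **Taxonomic turnover.** For pairs with |bNTI| <= 2, the Bray-Curtis-based
   Raup-Crick index (RCbray) compares observed Bray-Curtis dissimilarity to
   a null in which both communities are reassembled at their observed
   richness from the regional pool (presence proportional to occupancy,
   abundance proportional to pooled relative abundance). RCbray < -0.95
   indicates homogenizing dispersal, RCbray > +0.95 dispersal limitation,
   anything in between ecological drift; again strict inequalities, so
   RCbray = 0.95 is drift.

A prerequisite is verified first: niche optima must be phylogenetically
conserved. Optima are estimated as OTU scores on the first significant axis
of a canonical correspondence analysis on the environmental variables
(permutation tests, 999 permutations by default), and a Mantel correlogram
(Pearson correlations between optimum differences and cophenetic distances
in 30 equal-width classes, progressive Bonferroni correction) must show a
significantly positive correlation in the shortest distance classes. The
pipeline halts at this gate unless `force = TRUE`.

Classified pairs are then partitioned into comparison subsets — all pairs,
intra-lake (same ecosystem and year, different replicate), inter-lake
(same year, different ecosystems) and inter-year (same ecosystem, different
years); replicate pairs never enter the spatial or temporal subsets, and
pairs differing in both lake and year contribute only to "all". Within a
subset, occurrences of each process are converted to percentages per
replicate-combination comparison type, then averaged across types with
equal weight; the 95% CI uses the standard error across types. Differences
between subsets are tested with an exact two-sided permutation test on the
per-type percentages (Monte-Carlo with 1000 relabelings when exhaustive
enumeration exceeds a cap).

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `n_null` | 999 | null replicates for both null models; 199 is adequate for screening and what the packaged validation uses |
| bNTI thresholds | ±2 (strict) | standardized-effect cutoffs for selection |
| RCbray thresholds | ±0.95 (strict) | cutoffs for dispersal-driven turnover |
| `detection` | 0.1% (strict >) | relative abundance above which an OTU counts as present for core membership |
| `prevalence` | 75% (>=) | fraction of units (samples, lakes, years) required for core membership |
| abundance filter | 1% in >= 1 sample | OTUs entering the optima estimation |
| `n_classes` | 30 | Mantel correlogram distance classes |
| rarefaction depth | user-set (e.g. 7,690 reads) | even depth drawn without replacement; shallower samples are dropped with a warning |

## Design choices

Where the framework leaves details open, the package fixes them as follows.

* **betaMNTD weighting and null.** Abundance-weighted betaMNTD is the
  default (`weighted = FALSE` gives 1/richness weights). The null shuffles
  taxa across tip positions, one permutation per replicate applied to all
  pairs. By default the shuffle spans all tips of the supplied tree
  (`null_pool = "tree"`): the tree defines the regional species pool. When
  the tree is inferred from exactly the observed OTUs — the usual case with
  real data — this is identical to shuffling over observed taxa
  (`null_pool = "table"`). The distinction matters only when the tree
  deliberately includes unobserved pool members, as in the synthetic
  scenarios, where a filtered dataset carries no information about its own
  filtering unless the null can range over the full pool.
* **Degenerate pairs.** When the null SD of betaMNTD is below 1e-12 (e.g.
  identical communities), bNTI is undefined; the pair is flagged, labelled
  `undetermined`, and excluded from contribution denominators.
* **Raup-Crick ties and seeding.** Null Bray-Curtis values equal to the
  observed one within 1e-12 count half. Null substreams are seeded from the
  sorted sample-id pair, so RCbray is symmetric and independent of row
  order, and `assembly_fit()` may skip RCbray for selection-classified
  pairs (`rc_pairs = "needed"`) without changing any label.
* **Replicate-combination types.** Combos are unordered by default
  (`A-B` is `B-A`), giving three types for duplicate designs;
  `ordered_combos = TRUE` enumerates all four.
* **Shannon entropy** is reported in natural-log units.
* **Distance decay** reports OLS slope/intercept/R^2 over the selected
  pairs, with a Mantel-style permutation p (sample identities permuted,
  two-sided on |r|), since pairs sharing a sample are not independent.
* **PCoA** reports all eigenvalues; coordinates and proportions explained
  use the positive ones (proportions relative to their sum). Dispersion
  tests use `vegan::betadisper`, which applies the standard imaginary-axis
  correction.
* **Geographic distance** is haversine on a 6371-km sphere.
* **The 0.005% read filter** is applied dataset-wide with a strict `<`
  (equality retains); a per-sample variant is available via `scope`.
* **Spatial/temporal cores** collapse replicates to unit-level presence via
  "any replicate above detection" (a `mean` mode is provided), then apply
  the prevalence rule across lakes (within a year) or years (within a
  lake). Cumulative core abundance is relative to the unit's samples.

## The synthetic-community generator

Every stage is validated against `assemble_dataset()`, which emulates the
motivating survey design: by default 11 ecosystems x 4 years x duplicate
samples of one habitat, a regional pool of 300 OTUs on a pure-birth tree,
7,690 reads per sample, one environmental gradient. The packaged validation
uses a scaled design (8 ecosystems x 2 years x 2 replicates, 5,000 reads,
199 null replicates, three seeds) so the whole suite runs on a single CPU
in a few minutes; these sizes are the package's own choice of test
conditions.

The regional pool carries niche optima evolved by Brownian motion whose
rate decays toward the tips (`trait_conservatism`, an early-burst model):
niche positions are conserved at clade level, which is exactly the regime
in which nearest-taxon statistics are informative. Optima are standardized
to unit variance before filtering so the niche breadth
(`selection_strength`, in SD units) has a stable meaning. Pool relative
abundances are lognormal (`pool_evenness` = sdlog 2), a strongly
dominance-structured pool; this matters because the Raup-Crick null draws
presence by occupancy, and a pool without dominance structure leaves the
null with too little presence variance to distinguish convergent from
random assembly.

Each scenario is constructed so that the two-step classification should
recover it as the dominant label in its relevant comparison subset:

* **variable_selection** — Gaussian niche filtering of the pool around an
  environment value that differs among ecosystems (an even gradient across
  1.5 SD of the optima, with small inter-annual jitter). Inter-lake pairs
  straddle niches, so observed nearest-taxon distances exceed the null.
* **homogeneous_selection** — one harsh environment everywhere
  (`hs_env = 1.2` SD), a hard niche cutoff at 2 sigma, flattened
  within-niche dominance (`fitness_flattening = 0.25`: strong selection
  equalizes fitness among survivors), and a colonization lottery retaining
  half of the niche members per ecosystem-year. The lottery is essential:
  identically filtered communities share all taxa, leaving the
  nearest-taxon statistic nothing to measure — the clustering signal lives
  in the taxa the pair does not share.
* **dispersal_limitation** — per-ecosystem lognormal founder effects on
  the pool weights (`founder_sd = 2`), i.e. restricted colonization letting
  each lake drift to its own dominance structure. An earlier design that
  gave each ecosystem a private random subset of the pool with neutral
  weights turns out to be undetectable in principle: the occupancy-based
  Raup-Crick null reproduces the same expected overlap as the observed
  communities, so RCbray centres on zero. Founder effects keep the
  mechanism (limited exchange) while moving the signal into dominance
  structure, where the null can see it.
* **homogenizing_dispersal** — every sample is one multinomial draw from
  the common pool (mass effects): pairs are more similar than the null's
  richness-constrained reassembly, driving RCbray to -1.
* **drift** — each ecosystem-year lineage passes through serial
  bottleneck-and-regrowth cycles (5 cycles at 5% of the sample depth)
  before sampling; replicates add only multinomial noise. Divergence is
  random with respect to both phylogeny and the pool, landing within both
  null distributions.

What the generator does not emulate: sequencing error, chimeras,
compositional (relative-abundance) artefacts, taxonomic assignment error,
multi-variable environments (one synthetic gradient suffices to exercise
the optima machinery), or habitat-specific pools. Passing the packaged
validation therefore demonstrates that the estimator recovers known
processes under its own assumptions — not that any particular field
dataset satisfies those assumptions.

## Numerical and degenerate-input behaviour

Identity matching between table, tree and metadata is exact string
equality; `validate_dataset(strict = TRUE)` enumerates mismatches rather
than silently dropping them. Rarefaction is a seeded single draw without
replacement; samples below depth are dropped and listed. All randomized
stages derive named substreams from one master seed (31-bit polynomial
hashes), so per-pair results are order-independent and a full
`run_pipeline()` is byte-reproducible for a given config and seed.
Identical optima yield an untestable correlogram (flagged, never
significant) rather than an error; an empty stochastic-pair set is valid;
permutation p-values always include the observed statistic and are never
zero.

## Limitations

bNTI inherits the usual caveats: it requires genuine phylogenetic signal in
the traits under selection, and its power falls when communities share most
taxa or richness approaches the pool size. The contribution percentages
average over comparison types with equal weight, so types with few pairs
carry the same weight as large ones (matching the partitioning design, but
worth remembering with unbalanced designs). PERMANOVA is single-factor by
design — the pipeline tests one factor at a time per habitat;
sequential multi-factor decomposition is out of scope, as are variation
partitioning with spatial eigenvector predictors and discriminant analyses.
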