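---
title: "Null models for the drivers of microbial beta-diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models for the drivers of microbial beta-diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(betanull)
```

# The inference problem

Between-sample compositional dissimilarity (β-diversity) confounds two very
different kinds of cause. A larger regional species pool mechanically
inflates dissimilarity among random samples, with no ecology beyond sampling
involved; and local assembly processes — selection, dispersal, drift — push
dissimilarity above or below that sampling expectation. `betanull`
implements the chain of null models that separates these explanations for
rarefied taxa-by-sample count tables grouped into regions.

All stages consume a `community_table` (integer taxa × samples matrix plus a
sample → region map), built by `read_community_table()` and optionally
normalized by `rarefy()` (sampling without replacement, i.e. the
hypergeometric semantics of standard rarefaction; the target depth is a
user parameter because appropriate depths are dataset-specific).

# Diversity definitions

* **α**: observed richness of a sample (taxa with count > 0).
* **β**: mean pairwise Bray–Curtis dissimilarity among a region's samples,
  `BC(x, y) = Σ|x_i − y_i| / Σ(x_i + y_i)`, computed on rarefied counts.
  With equal depths this equals the relative-abundance form; computing on
  counts avoids a silent renormalization. The mean is the plain arithmetic
  mean over unordered pairs.
* **γ**: pooled observed richness of the region. No richness extrapolation
  is applied — γ is a pool-size proxy, not an asymptotic estimate.

# The two constrained null models and β-deviation

Both schemes permute each region independently, conserving each sample's
observed richness and total count, and differ in what else they conserve:

* **Model I** (conditions on γ only): each null sample draws its observed
  richness of taxa uniformly without replacement from the region's γ taxa
  and receives its own observed non-zero abundance values in random order.
  Abundance-value multisets per sample are conserved exactly.
* **Model II** (conditions on the pool): taxa are drawn without replacement
  with probability proportional to their occurrence frequency (`sp_freq`,
  the number of region samples containing the taxon), using sequential
  draws with renormalization (the semantics of R's weighted `sample()`);
  abundances are refilled as one guaranteed individual per drawn taxon plus
  a multinomial allocation of the remainder proportional to the pooled
  relative abundances renormalized over the drawn taxa.

For each scheme, the expected β is the mean pairwise Bray–Curtis of each
permuted table, over `n_perm = 1000` permutations by default, and

```
β-deviation = (β_obs − mean(β_null)) / SD(β_null)
```

with the sample (n−1) standard deviation, the usual SES convention. A zero
null spread (e.g. a single-taxon region) yields a flagged `NA` with a
warning rather than an error. The sign is read qualitatively
(`interpret_deviation()`): positive → heterogeneous selection or dispersal
limitation; negative → homogeneous selection or homogenizing dispersal;
within ±0.05 of zero (configurable) → drift.

A consistency subtlety worth knowing: a β-deviation is self-consistent (mean
ses ≈ 0) when the observed table is itself a draw from the null ensemble it
is compared against. If the analysis re-estimates the conditioning
statistics from a table that was generated under *different* conditioning
(as any real analysis implicitly does), model II acquires a finite-sample
offset because the pool statistics are themselves random. The acceptance
suite therefore checks exchangeability — observed and null draws conditioned
on the same pool — which is the property the method actually promises.

# Expected β–γ under random sampling

`expected_beta_gamma()` asks what β would be with no assembly at all: for
each γ on a grid, draw a lognormal species-abundance distribution
(`meanlog = 0`, `sdlog = 1` by default; these are conventional,
dataset-calibratable values), normalize, draw pairs of multinomial samples
of `n` individuals, and average Bray–Curtis over replicates. The pool is
redrawn every replicate, so the curve marginalizes over SAD realizations
rather than conditioning on one. Monte-Carlo standard errors are reported
alongside the means, and the suite's shape assertions (zero at γ = 1,
non-decreasing in γ, decreasing in n) are made within one MC standard error.

# Phylogenetic and probabilistic process partitioning

Per within-region sample pair (`process_metrics()`):

* **βMNTD**: for each taxon present in one sample, the minimum patristic
  distance to any taxon present in the other; the two directional
  abundance-weighted means are averaged. Abundance weighting is the default
  (matching the abundance-based workflow elsewhere in the package);
  presence weighting is available for diagnostics.
* **βNTI**: SES of βMNTD against `n_null = 999` tip-label shuffles. The
  shuffle spans the **study-level taxon set** — all taxa of the table that
  appear in the phylogeny — not just the region's observed taxa. This is a
  deliberate design decision: selection filters the regional community out
  of a wider pool, so a shuffle restricted to the taxa selection let
  through has, by construction, no contrast left to detect (we verified on
  synthetic selection scenarios that the region-restricted shuffle yields
  βNTI ≈ 0 or even positive values driven by trait-band edge turnover).
  One set of shuffles is shared by all pairs of a region, the standard
  region-level formulation.
* **RC_bray**: null assemblies conditioned on each sample's observed
  richness and total, with occurrence-frequency-weighted taxon draws and
  pool-proportional abundance refill (the model II per-sample scheme, which
  is also the widely used modified Raup–Crick formulation). With ties given
  half weight, `RC = 2((#{null < obs} + 0.5·#{null = obs})/n_null − 0.5)`
  ∈ [−1, 1]. One set of whole-region null assemblies is shared across
  pairs. The Raup–Crick pool is the *region* (per-region partitions), while
  the βNTI shuffle is study-wide; the two nulls answer different questions
  and deliberately use different scopes.
* **Classification** (`classify_process()`): βNTI < −2 → homogeneous
  selection; βNTI > 2 → heterogeneous selection; otherwise RC < −0.95 →
  homogenizing dispersal; RC > 0.95 → dispersal limitation; |RC| ≤ 0.95 →
  drift. Boundaries are inclusive on the "no signal" side (|βNTI| = 2 and
  |RC| = 0.95 are *not* treated as selection/dispersal), and both
  thresholds are overridable parameters. Pairs with a degenerate βNTI null
  (e.g. a star phylogeny) are excluded from `partition_processes()`
  fractions with a logged count.

# Environmental analysis

Variables are z-scored per column (n−1 denominator; constant columns are an
error naming the variable). Environmental heterogeneity is the Euclidean
distance on the standardized matrix. `beta_env_association()` fits ordinary
least squares on the pairwise vectors but takes its p-value from a
Mantel-style permutation of *sample* labels (999 by default, two-sided on
the correlation), because pairwise values are not independent.

`dbrda()` re-implements constrained ordination from its definition:
principal-coordinates embedding of the dissimilarity matrix (double-centre
−½·J·D²·J, eigendecompose, keep axes with positive eigenvalues), then
regression of the coordinates on the centred environmental variables.
`R² = ‖HY‖²/‖Y‖²`. Negative eigenvalues are dropped by default and their
summed magnitude reported (`negative_inertia`); the Lingoes correction is
available by flag. The global test permutes sample rows; marginal
per-variable tests permute residuals under the reduced model omitting that
variable. All sums of squares are computed as norms of projections, so
exact-fit configurations (rank-one dissimilarities) yield `F = Inf` rather
than sign errors from floating-point cancellation. Against `vegan`'s
`capscale` on the same inputs, the global F statistic agrees to numerical
precision and R² to within the differing treatment of near-zero axes.

# The synthetic generator: what it emulates and what it does not

`simulate_pool()` builds a regional pool: lognormal relative abundances, a
pure-birth phylogeny (`ape::rphylo`), and a niche trait evolved by Brownian
motion along the tree. The trait is mapped to niche optima in [0, 1] by a
**rank-uniform** transform — monotone, so phylogenetic ordering is
preserved, while a Gaussian filter of fixed width always selects the same
fraction of the pool wherever it is centred (a min–max scaling concentrates
optima and makes filter selectivity depend on the tree realization).

`assemble_region()` draws every sample as one multinomial of `depth`
individuals (default 5,000 — large enough for stable Bray–Curtis, small
enough for desk-scale runs; 12 samples per region by default). Process
distortions, with effect strength `s ∈ [0, 1]` and Gaussian filter width
`w = 1 − s(1 − 0.05)`:

* **HoS**: one filter position for all samples, by default 0.05 — an
  extreme habitat. Design rationale: an extreme anchor selects the
  phylogenetically compact lineage that has drifted furthest along the
  trait, which is what makes homogeneous selection *visible* to βNTI; a
  mid-gradient anchor selects trait-convergent taxa from many clades and
  the signal is fragile across tree realizations.
* **HeS**: the same filter with samples spread evenly across [0.05, 0.95].
* **Selection turnover**: both selection processes additionally hide a
  random fraction (`turnover = s/3` by default) of the pool from each
  sample — stochastic colonist availability. Without it, deep equal-weight
  sampling saturates the selected band in every sample; the only unshared
  taxa are band-edge taxa, and βNTI is biased *positive*. With
  `turnover = 0` the generator is the pure filter, and then selection
  strictly *lowers* within-region β relative to the neutral baseline (the
  property the unit suite asserts); with the default turnover the
  between-sample membership turnover needed for phylogenetic detectability
  raises β instead. Both regimes are tested.
* **DL**: neutral weights restricted to a contiguous window of length
  `γ(1 − 0.8s)` at a random circular offset in a *seeded random* taxon
  order. A tree-traversal order (available as `dl_order = "tree"`) makes
  windows contiguous clades, i.e. phylogenetically clustered communities
  that βNTI reads as selection — contradicting the intent of a dispersal
  kernel with no niche signal — so random order is the default.
* **HD**: a fraction `s` of every sample's individuals is one shared
  multinomial source draw (mass effects); the rest are independent.
* **DR**: a demographic bottleneck — an effective community of
  `depth(1 − 0.2s)` individuals (floor 100) is drawn and rescaled to
  `depth`. The 20% cap is deliberate: a richness-conditioned Raup–Crick
  null attributes only a bounded amount of abundance scatter to chance, so
  stronger bottlenecks leave the stochastic envelope and are — by the
  partition's own definition — dispersal limitation, not drift. Drift
  beyond that envelope is *not identifiable* within this framework, and the
  generator does not pretend otherwise.
* `s = 0` collapses every process to identical neutral sampling (same seed,
  same table).

What a green recovery test establishes: that each process, at strength 0.9
under these mechanisms, leaves the signature the partition framework
expects, and that the largest fraction of pairs is assigned to the true
process. What it does not establish: correct behaviour on real data with
compositional artefacts, sequencing error, taxon-dependent detection, or
multiple interacting processes — none of which the generator emulates. The
recovery of homogeneous selection is the least robust margin: across
generator seeds its βNTI distribution sits near the −2 threshold, and some
pool realizations leave the drift label with the plurality. The acceptance
scenario uses the suite's documented default seed; this sensitivity is a
property of tip-shuffle SES at 12-sample scale, not of the implementation.

# Numerical and interface choices

* Explicit integer seeds everywhere; internal stages derive child seeds by
  a fixed affine map, so no stage consumes another's stream; all seeds stay
  below 2³¹.
* SES denominators use n−1 throughout. Zero null spread → flagged `NA` +
  warning, never silent.
* Ties in RC take half weight (documented because it shifts boundary
  classifications).
* Rarefaction: samples below depth are an error by default;
  `drop_shallow = TRUE` discards them with a warning. Missing environmental
  values: rejected by default, mean-imputed by flag.
* All-zero taxon rows are retained in tables but excluded from γ and pools;
  all-zero sample columns are rejected at load.
* βMNTD inner loops are in C++ (Rcpp); one `O(G · n_j)` sweep per sample
  per shuffle makes 999 randomizations affordable at γ = 500.
* The CLI (`run_cli()`) mirrors the R API one subcommand per stage; `run`
  executes the whole chain and writes a JSON manifest with every parameter
  and seed needed to regenerate its outputs. Config files are JSON with
  precedence CLI > file > defaults.

# Known limitations

* γ is observed pooled richness; no extrapolated pool size.
* The β–environment association and db-RDA assume one global structure; no
  variation partitioning or variable selection is provided.
* The partition treats pairs independently; no bin-based within-clade
  refinement.
* Cross-region pairs are never classified (the region is the assembly
  arena for Raup–Crick).
* The generator's environmental table carries the single gradient that
  drove assembly (plus whatever the user appends); it does not emulate the
  full multivariate physicochemical suites of field studies.
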