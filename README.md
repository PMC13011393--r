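# betanull

Null-model inference for the drivers of microbial β-diversity.

## The problem

Amplicon surveys routinely find that community dissimilarity (β-diversity)
varies across regions, but the observation alone cannot say *why*: a large
regional species pool (γ-diversity) inflates β under pure random sampling,
while local community assembly — selection, dispersal, drift — moves β away
from that sampling expectation. `betanull` implements the standard
null-model chain used to disentangle these drivers for taxa-by-sample ASV
tables:

1. **α/β/γ diversity** — observed richness per sample, mean pairwise
   Bray–Curtis dissimilarity within a region
   (`BC(x,y) = Σ|x_i − y_i| / Σ(x_i + y_i)`), and pooled regional richness.
2. **Constrained taxonomic null models** and the **β-deviation**
   standardized effect size,

   ```
   β-deviation = (β_obs − mean(β_null)) / SD(β_null)
   ```

   under two conditioning schemes: **model I** conserves only per-sample
   richness and the regional γ (uniform taxon draws, within-sample abundance
   shuffles); **model II** additionally conserves the pool's occurrence
   frequencies and pooled relative abundances (weighted draws, pool-
   proportional refill). Positive deviations indicate heterogeneous
   selection or dispersal limitation; negative ones homogeneous selection or
   homogenizing dispersal; ≈0 indicates drift.
3. **Expected β–γ curves** under pure random sampling from lognormal species
   abundance distributions — the no-assembly baseline.
4. **Process partitioning** per sample pair with phylogenetic and
   probabilistic nulls: βNTI (tip-shuffle SES of abundance-weighted βMNTD)
   and modified Raup–Crick on Bray–Curtis (RC_bray). Pairs are classified
   as homogeneous selection (βNTI < −2), heterogeneous selection (βNTI > 2),
   homogenizing dispersal (RC < −0.95), dispersal limitation (RC > 0.95) or
   drift (otherwise).
5. **Environmental analysis** — z-scored variables, Euclidean heterogeneity,
   Mantel-style β–environment association, and distance-based redundancy
   analysis (db-RDA) built from its definition (PCoA embedding + constrained
   regression with permutation tests).
6. **A process-labelled synthetic generator** (lognormal pools, pure-birth
   phylogenies, Brownian niche traits, five assembly processes at tunable
   strength) so the whole chain is testable without any sequencing data.

Who it is for: microbial ecologists with rarefied ASV/OTU tables, a sample →
region mapping, and optionally a phylogeny and environmental measurements.

## Worked example

One region shaped by heterogeneous selection: 12 samples along an
environmental gradient, a 200-taxon pool, 2,000 reads per sample.

```r
library(betanull)

sc  <- simulate_scenario("HeS", strength = 0.9, gamma = 200, n_samples = 12,
                         depth = 2000, seed = 42)
div <- regional_diversity(sc$table, "R_HeS")
div
#> region 'R_HeS': gamma = 200, mean alpha = 89.0, mean pairwise BC = 0.7522 (66 pairs)

deviation_summary(sc$table, n_perm = 1000, seed = 7)
#>  region   scheme beta_obs null_mean null_sd   ses  label
#>   R_HeS  MODEL_I    0.752     0.828 0.00432 -17.6 HoS/HD
#>   R_HeS MODEL_II    0.752     0.557 0.01490  13.1 HeS/DL

met <- process_metrics(sc$table, "R_HeS", sc$tree, n_null = 999, seed = 7)
partition_processes(met)
#>  region n_pairs   HeS   HoS HD    DL    DR
#>   R_HeS      66 0.409 0.121  0 0.258 0.212
```

Reading the output: observed β (0.752) sits *below* the γ-conditioned null
(model I: identity-scrambled communities are even more dissimilar than the
niche-sorted ones) but far *above* the pool-conditioned null (model II:
+13.1 SD), the signature of local assembly structuring β beyond what the
regional pool explains. The pairwise partition attributes the largest share
of sample pairs (41%) to heterogeneous selection — the process the generator
actually used — with the spread across neighbouring gradient positions
diluting into DL/DR labels for environmentally similar pairs.

## Command line

Every stage is also a subcommand:

```sh
Rscript -e 'betanull::run_cli()' simulate --process HeS --strength 0.9 \
    --gamma 200 --samples 12 --depth 2000 --seed 42 --out-dir demo/
Rscript -e 'betanull::run_cli()' diversity --in demo/community.tsv \
    --meta demo/metadata.tsv --out-dir demo/out
Rscript -e 'betanull::run_cli()' run --in demo/community.tsv \
    --meta demo/metadata.tsv --tree demo/tree.nwk --env demo/env.tsv \
    --scheme both --n-perm 1000 --seed 1 --out-dir demo/out
```

Subcommands: `rarefy`, `diversity`, `deviation`, `expected-curve`,
`partition`, `envhet`, `dbrda`, `simulate`, `run`. File formats are plain
TSV (taxa × samples with a `taxon_id` column; metadata with
`sample`/`region`/`latitude`), newick trees, and a JSON run manifest.

## Documentation

The methods vignette (`vignettes/assembly-null-models.Rmd`) describes the
models, the two null schemes, the threshold conventions, what the synthetic
generator does and does not emulate, and the numerical design choices.
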