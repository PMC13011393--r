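## Process-labelled synthetic communities.
##
## A regional species pool is a lognormal species-abundance distribution over
## gamma taxa, a pure-birth phylogeny over those taxa, and niche optima
## evolved by Brownian motion along the tree (so niche traits are
## phylogenetically conserved, which is what gives betaNTI its signal).
## Local communities are multinomial draws from the pool, distorted by one of
## the five assembly processes.

## Rank-uniform rescaling of the Brownian trait to [0, 1]: a monotone
## transform, so the phylogenetic ordering of niche optima is preserved while
## the niche axis is occupied uniformly (a fixed-width Gaussian filter then
## always selects the same fraction of the pool, wherever it is centred).
rank01 <- function(x) (rank(x, ties.method = "first") - 0.5) / length(x)

#' Simulate a regional species pool
#'
#' @param gamma number of taxa (>= 2).
#' @param sad_params lognormal abundance parameters `c(meanlog, sdlog)`.
#' @param birth_rate pure-birth speciation rate of the phylogeny.
#' @param brownian_rate Brownian-motion rate (variance per unit branch
#'   length) of the niche trait.
#' @param seed integer seed.
#' @return list: `taxa` (ids), `pool_rel_abund` (named, sums to 1), `tree`
#'   (`phylo`), `niche_optima` (named, rank-uniform rescaling of the Brownian
#'   trait to \[0, 1\]; monotone, so phylogenetic ordering is preserved),
#'   `traits` (raw Brownian tip values).
#' @export
simulate_pool <- function(gamma, sad_params = c(meanlog = 0, sdlog = 1),
                          birth_rate = 1, brownian_rate = 1, seed) {
  gamma <- assert_scalar_int(gamma, "gamma", min = 2L)
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    tree <- ape::rphylo(gamma, birth = birth_rate, death = 0)
    tree$tip.label <- sprintf("t%05d", seq_len(gamma))
    ab <- rlnorm(gamma, sad_params[[1L]], sad_params[[2L]])
    traits <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(brownian_rate))
  })
  names(ab) <- tree$tip.label
  list(taxa = tree$tip.label,
       pool_rel_abund = ab / sum(ab),
       tree = tree,
       niche_optima = stats::setNames(rank01(traits), tree$tip.label),
       traits = traits)
}

## Gaussian niche filter: weight of a taxon at environmental position e.
## Width shrinks linearly with effect strength; strength 0 is the neutral
## (no-filter) limit.
filter_width <- function(strength, w_max = 1, w_min = 0.05) {
  w_max - strength * (w_max - w_min)
}

#' Assemble one region's samples under a stated process
#'
#' Every sample is a multinomial draw of `depth` individuals. Sampling
#' weights are the pool relative abundances, distorted by the process:
#' \describe{
#'   \item{HoS}{Gaussian niche filter `exp(-(optimum - env)^2 / (2 w^2))`
#'     with all samples at the same environmental position (default 0.05, an
#'     extreme habitat selecting a phylogenetically conserved specialist
#'     clade).}
#'   \item{HeS}{the same filter with samples spread across the gradient.}
#'   \item{DL}{neutral weights, but each sample only sees a contiguous window
#'     of the taxon pool (a colonization kernel) of length
#'     `gamma * (1 - 0.8 * strength)` at a random circular offset.}
#'   \item{HD}{a fraction `strength` of every sample's individuals comes from
#'     one shared multinomial source draw (mass effects), the rest from
#'     independent draws.}
#'   \item{DR}{neutral weights through a demographic bottleneck: an effective
#'     community of `depth * (1 - 0.2 * strength)` individuals (floor 100) is
#'     drawn first and rescaled to `depth`. The bottleneck is capped at a 20%
#'     reduction because stronger drift pushes observed turnover outside the
#'     stochastic envelope of the richness-conditioned Raup-Crick null, which
#'     the partition by definition reads as dispersal limitation.}
#' }
#' For the selection processes, each sample additionally sees only a random
#' subset of the pool (`turnover`, the fraction of taxa unavailable to a
#' given sample; stochastic colonist availability). Without it, deep
#' equal-weight sampling saturates the selected trait band in every sample,
#' leaving only band-edge taxa unshared and erasing the within-clade
#' turnover that phylogenetic nulls detect selection by. `turnover = 0`
#' recovers the pure filter. `strength = 0` reduces every process to neutral
#' multinomial sampling.
#'
#' @param pool a [simulate_pool()] result.
#' @param process one of `"HoS"`, `"HeS"`, `"DL"`, `"HD"`, `"DR"`.
#' @param strength effect strength in \[0, 1\].
#' @param n_samples samples in the region (default 12).
#' @param depth individuals per sample (default 5000).
#' @param env_values optional environmental positions (length `n_samples`,
#'   in \[0, 1\]); defaults depend on the process (constant 0.05 for HoS, an
#'   even spread otherwise).
#' @param seed integer seed.
#' @param turnover fraction of pool taxa unavailable to each sample under the
#'   selection processes; default `strength / 3`.
#' @param dl_order taxon ordering used by the DL window: `"random"` (a fixed
#'   seeded permutation; the default, giving spatial turnover with no
#'   phylogenetic signal) or `"tree"` (tip order, which makes the windows
#'   phylogenetically clustered and bleeds into the selection signal).
#' @return list: `counts` (gamma x n_samples integer matrix, taxa as rows),
#'   `env_values`, `process`, `strength`.
#' @export
assemble_region <- function(pool, process = c("HoS", "HeS", "DL", "HD", "DR"),
                            strength, n_samples = 12L, depth = 5000L,
                            env_values = NULL, seed, turnover = strength / 3,
                            dl_order = "random") {
  process <- match.arg(process)
  n_samples <- assert_scalar_int(n_samples, "n_samples", min = 2L)
  depth <- assert_scalar_int(depth, "depth")
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  if (strength < 0 || strength > 1) stop("'strength' must be in [0, 1]",
                                         call. = FALSE)
  if (turnover < 0 || turnover >= 1) stop("'turnover' must be in [0, 1)",
                                          call. = FALSE)
  gamma <- length(pool$taxa)
  if (is.null(env_values)) {
    env_values <- if (process == "HoS") rep(0.05, n_samples)
                  else seq(0.05, 0.95, length.out = n_samples)
  }
  if (length(env_values) != n_samples)
    stop("'env_values' must have length n_samples", call. = FALSE)
  base <- pool$pool_rel_abund
  counts <- withr::with_seed(seed, {
    if (strength == 0) {
      vapply(seq_len(n_samples), function(s) rmultinom(1L, depth, base)[, 1L],
             integer(gamma))
    } else if (process %in% c("HoS", "HeS")) {
      w <- filter_width(strength)
      vapply(seq_len(n_samples), function(s) {
        wt <- base * exp(-(pool$niche_optima - env_values[s])^2 / (2 * w^2))
        if (turnover > 0) {
          masked <- wt * (runif(gamma) >= turnover)
          if (sum(masked) > 0) wt <- masked
        }
        rmultinom(1L, depth, wt)[, 1L]
      }, integer(gamma))
    } else if (process == "DL") {
      ord <- if (identical(dl_order, "tree")) seq_len(gamma)
             else sample.int(gamma)
      len <- max(1L, round(gamma * (1 - 0.8 * strength)))
      vapply(seq_len(n_samples), function(s) {
        off <- sample.int(gamma, 1L)
        win <- ord[((off + seq_len(len) - 2L) %% gamma) + 1L]
        wt <- numeric(gamma)
        wt[win] <- base[win]
        rmultinom(1L, depth, wt)[, 1L]
      }, integer(gamma))
    } else if (process == "HD") {
      n_shared <- round(strength * depth)
      shared <- rmultinom(1L, n_shared, base)[, 1L]
      vapply(seq_len(n_samples), function(s) {
        shared + rmultinom(1L, depth - n_shared, base)[, 1L]
      }, integer(gamma))
    } else { # DR
      n_eff <- max(100L, round(depth * (1 - 0.2 * strength)))
      vapply(seq_len(n_samples), function(s) {
        bottleneck <- rmultinom(1L, n_eff, base)[, 1L]
        rmultinom(1L, depth, bottleneck / n_eff)[, 1L]
      }, integer(gamma))
    }
  })
  rownames(counts) <- pool$taxa
  list(counts = counts, env_values = env_values, process = process,
       strength = strength)
}

#' Generate one process-labelled scenario dataset
#'
#' One region of `n_samples` local communities assembled from a simulated
#' pool under a single ground-truth process, packaged with its phylogeny and
#' a one-variable environmental table, ready for the full inference chain.
#'
#' @inheritParams assemble_region
#' @inheritParams simulate_pool
#' @param region region label (default derived from the process).
#' @return object of class `scenario_truth`: `table` (`community_table`),
#'   `tree`, `env` (samples x 1 matrix, variable `gradient`), `process`,
#'   `params` (generator parameters incl. seed).
#' @export
simulate_scenario <- function(process, strength = 0.9, gamma = 500L,
                              n_samples = 12L, depth = 5000L,
                              sad_params = c(meanlog = 0, sdlog = 1),
                              brownian_rate = 1, seed, region = NULL,
                              pool = NULL) {
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  if (is.null(pool))
    pool <- simulate_pool(gamma, sad_params, brownian_rate = brownian_rate,
                          seed = derive_seed(seed, 7L))
  reg <- assemble_region(pool, process, strength, n_samples, depth,
                         seed = derive_seed(seed, 13L))
  region <- region %||% paste0("R_", process)
  samples <- sprintf("%s_s%02d", region, seq_len(n_samples))
  colnames(reg$counts) <- samples
  tab <- community_table(reg$counts,
                         stats::setNames(rep(region, n_samples), samples),
                         stats::setNames(reg$env_values * 30 + 10, samples))
  env <- matrix(reg$env_values, ncol = 1L,
                dimnames = list(samples, "gradient"))
  structure(list(table = tab, tree = pool$tree, env = env, process = process,
                 params = list(strength = strength, gamma = gamma,
                               n_samples = n_samples, depth = depth,
                               sad_params = sad_params, seed = seed)),
            class = "scenario_truth")
}

#' Generate the five-process scenario suite
#'
#' One dataset per assembly process, all sharing the same regional pool
#' (taxa, abundances, phylogeny, niche optima) and sampling depth so that the
#' process is the only difference between them.
#'
#' @inheritParams simulate_scenario
#' @param processes process labels to generate.
#' @return named list of `scenario_truth` objects.
#' @export
scenario_suite <- function(processes = c("HoS", "HeS", "DL", "HD", "DR"),
                           strength = 0.9, gamma = 500L, n_samples = 12L,
                           depth = 5000L,
                           sad_params = c(meanlog = 0, sdlog = 1),
                           brownian_rate = 1, seed) {
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  pool <- simulate_pool(gamma, sad_params, brownian_rate = brownian_rate,
                        seed = derive_seed(seed, 7L))
  out <- lapply(seq_along(processes), function(i) {
    simulate_scenario(processes[i], strength, gamma, n_samples, depth,
                      sad_params, brownian_rate,
                      seed = derive_seed(seed, 100L + i), pool = pool)
  })
  stats::setNames(out, processes)
}

#' Write a scenario dataset to the standard file formats
#'
#' Emits `community.tsv`, `metadata.tsv`, `env.tsv`, `tree.nwk` and
#' `truth.json` under `out_dir`.
#'
#' @param scenario a `scenario_truth`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_scenario <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "scenario_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_community_table(scenario$table,
                        file.path(out_dir, "community.tsv"),
                        file.path(out_dir, "metadata.tsv"))
  env_df <- data.frame(sample = rownames(scenario$env), scenario$env,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(env_df, file.path(out_dir, "env.tsv"))
  ape::write.tree(scenario$tree, file.path(out_dir, "tree.nwk"))
  jsonlite::write_json(c(list(process = scenario$process), scenario$params),
                       file.path(out_dir, "truth.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
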