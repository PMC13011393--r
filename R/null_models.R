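## Constrained taxonomic null models and the beta-deviation standardized
## effect size.
##
## Two permutation schemes, mirroring the classic "which pool property is
## conserved" contrast:
##   MODEL_I  - conditions on gamma only: each null sample draws its observed
##              richness of taxa uniformly from the regional taxon set and
##              receives its own observed non-zero abundance values in random
##              order (per-sample totals and abundance multisets conserved).
##   MODEL_II - additionally conditions on the pool structure: taxa are drawn
##              without replacement with probability proportional to their
##              occurrence frequency (sp_freq), one individual is placed on
##              each drawn taxon, and the remaining individuals are allocated
##              multinomially proportional to the pooled relative abundances
##              renormalized over the drawn taxa.

## One MODEL_I null sample: permuted observed abundances on a uniform taxon draw.
null_sample_model_I <- function(values, gamma) {
  out <- numeric(gamma)
  idx <- sample.int(gamma, length(values))
  out[idx] <- if (length(values) > 1L) sample(values) else values
  out
}

## One MODEL_II / Raup-Crick null sample: sp_freq-weighted taxon draw,
## one guaranteed individual per taxon, multinomial fill of the remainder.
null_sample_model_II <- function(rich, total, sp_freq, pool_rel_abund) {
  gamma <- length(sp_freq)
  out <- numeric(gamma)
  idx <- if (rich >= gamma) seq_len(gamma)
         else sample.int(gamma, rich, prob = sp_freq)
  p <- pool_rel_abund[idx]
  out[idx] <- 1 + rmultinom(1L, total - length(idx), p / sum(p))[, 1L]
  out
}

null_region_table <- function(scheme, pool, obs = NULL) {
  gamma <- pool$gamma
  m <- matrix(0, gamma, pool$n_samples)
  for (s in seq_len(pool$n_samples)) {
    m[, s] <- if (scheme == "MODEL_I")
      null_sample_model_I(obs[obs[, s] > 0, s], gamma)
    else
      null_sample_model_II(pool$samp_rich[s], pool$samp_total[s],
                           pool$sp_freq, pool$pool_rel_abund)
  }
  m
}

null_ensemble <- function(table, region, scheme, n_perm, seed, keep_tables) {
  n_perm <- assert_scalar_int(n_perm, "n_perm")
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  pool <- pool_region(table, region)
  obs <- region_counts(table, region, drop_empty_taxa = TRUE)
  withr::with_seed(seed, {
    tabs <- vector("list", if (keep_tables) n_perm else 0L)
    nbm <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      nt <- null_region_table(scheme, pool, obs)
      nbm[r] <- mean_pairwise_bray(nt)
      if (keep_tables) {
        dimnames(nt) <- dimnames(obs)
        tabs[[r]] <- nt
      }
    }
  })
  structure(list(region = region, scheme = scheme, n_perm = n_perm,
                 null_beta_means = nbm, null_tables = tabs, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble (%s) for region '%s': %d permutations, mean null beta = %.4f\n",
              x$scheme, x$region, x$n_perm, mean(x$null_beta_means)))
  invisible(x)
}

#' Null model I: conditioned on gamma-diversity
#'
#' For each permutation and each sample, the sample's observed richness of
#' taxa is drawn uniformly without replacement from the regional taxon set,
#' and the sample's observed non-zero abundance values are assigned to the
#' drawn taxa in random order. Per-sample richness, totals and
#' abundance-value multisets are conserved; only taxon identities (and hence
#' overlaps between samples) are randomized.
#'
#' @inheritParams region_counts
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param keep_tables retain the permuted tables (memory-heavy; used by the
#'   validation suite).
#' @return a `null_ensemble` with `null_beta_means`, the per-permutation mean
#'   pairwise Bray-Curtis dissimilarity.
#' @export
null_model_I <- function(table, region, n_perm = 1000L, seed,
                         keep_tables = FALSE) {
  null_ensemble(table, region, "MODEL_I", n_perm, seed, keep_tables)
}

#' Null model II: conditioned on the regional species pool
#'
#' As [null_model_I()], but taxon draws are weighted by occurrence frequency
#' and abundances are refilled from the pooled relative abundances: one
#' individual per drawn taxon plus a multinomial allocation of the remaining
#' individuals with probabilities proportional to the pooled relative
#' abundances renormalized over the drawn taxa. Per-sample richness and
#' totals are conserved.
#'
#' @inheritParams null_model_I
#' @return a `null_ensemble`.
#' @export
null_model_II <- function(table, region, n_perm = 1000L, seed,
                          keep_tables = FALSE) {
  null_ensemble(table, region, "MODEL_II", n_perm, seed, keep_tables)
}

#' Beta-deviation: standardized effect size of beta-diversity
#'
#' \deqn{\beta\text{-deviation} = \frac{\beta_{obs} - \bar\beta_{null}}{SD(\beta_{null})}}
#'
#' with the sample (n-1) standard deviation over the ensemble's permuted mean
#' pairwise Bray-Curtis values. A zero null spread yields a flagged undefined
#' deviation with a warning rather than an error.
#'
#' @param beta_obs observed mean pairwise Bray-Curtis dissimilarity.
#' @param ensemble a `null_ensemble`.
#' @return object of class `beta_deviation`: list with `region`, `scheme`,
#'   `beta_obs`, `null_mean`, `null_sd`, `ses`, `degenerate`.
#' @export
beta_deviation <- function(beta_obs, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  nb <- ensemble$null_beta_means
  if (!length(nb)) stop("empty null ensemble", call. = FALSE)
  mu <- mean(nb)
  s <- sd(nb)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate)
    warning("null ensemble has zero spread; beta-deviation undefined")
  structure(list(region = ensemble$region, scheme = ensemble$scheme,
                 beta_obs = beta_obs, null_mean = mu, null_sd = s,
                 ses = if (degenerate) NA_real_ else (beta_obs - mu) / s,
                 degenerate = degenerate),
            class = "beta_deviation")
}

#' @export
print.beta_deviation <- function(x, ...) {
  cat(sprintf("beta-deviation (%s, region '%s'): beta_obs = %.4f, null = %.4f +- %.4f, ses = %.3f\n",
              x$scheme, x$region, x$beta_obs, x$null_mean, x$null_sd, x$ses))
  invisible(x)
}

#' Qualitative reading of a beta-deviation
#'
#' A positive deviation indicates beta-diversity driven primarily by
#' heterogeneous selection or dispersal limitation; a negative one by
#' homogeneous selection or homogenizing dispersal; a (near-)zero one by
#' stochastic drift.
#'
#' @param ses finite beta-deviation value.
#' @param tol half-width of the "indistinguishable from zero" band.
#' @return one of `"HeS/DL"`, `"HoS/HD"`, `"drift"`.
#' @export
interpret_deviation <- function(ses, tol = 0.05) {
  if (!is.finite(ses)) stop("'ses' must be finite", call. = FALSE)
  if (abs(ses) < tol) "drift" else if (ses > 0) "HeS/DL" else "HoS/HD"
}

#' Per-region beta-deviation table
#'
#' Runs the requested null scheme(s) for every region of a table and collects
#' the deviations.
#'
#' @inheritParams null_model_I
#' @param table a `community_table`.
#' @param schemes subset of `c("MODEL_I", "MODEL_II")`.
#' @param tol zero-band passed to [interpret_deviation()].
#' @return data.frame: `region`, `scheme`, `beta_obs`, `null_mean`, `null_sd`,
#'   `ses`, `label`.
#' @export
deviation_summary <- function(table, schemes = c("MODEL_I", "MODEL_II"),
                              n_perm = 1000L, seed, tol = 0.05) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  rows <- list()
  for (r in regions(table)) {
    beta_obs <- regional_diversity(table, r)$beta_mean
    for (sc in schemes) {
      fun <- if (sc == "MODEL_I") null_model_I else null_model_II
      ens <- fun(table, r, n_perm = n_perm,
                 seed = derive_seed(seed, match(sc, schemes) * 1000L +
                                      match(r, regions(table))))
      dev <- beta_deviation(beta_obs, ens)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, scheme = sc, beta_obs = beta_obs,
        null_mean = dev$null_mean, null_sd = dev$null_sd, ses = dev$ses,
        label = if (is.finite(dev$ses)) interpret_deviation(dev$ses, tol)
                else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Expected beta-gamma relationship under random sampling
#'
#' For each gamma on a grid, builds a species pool of gamma taxa with
#' lognormal relative abundances, draws pairs of samples of `n_individuals`
#' each (multinomial random sampling with no assembly process), and averages
#' their Bray-Curtis dissimilarity over replicates. The pool is redrawn for
#' every replicate. This is the expected beta-diversity attributable to the
#' regional pool size alone.
#'
#' @param gamma_grid increasing vector of pool sizes.
#' @param n_individuals individuals sampled per local community.
#' @param sad_params lognormal species-abundance parameters,
#'   `c(meanlog, sdlog)` on the log scale.
#' @param reps replicate pool/pair draws per gamma.
#' @param seed integer seed.
#' @return data.frame: `gamma`, `n`, `expected_beta`, `mc_se` (Monte-Carlo
#'   standard error).
#' @export
expected_beta_gamma <- function(gamma_grid, n_individuals,
                                sad_params = c(meanlog = 0, sdlog = 1),
                                reps = 200L, seed) {
  if (is.unsorted(gamma_grid, strictly = TRUE))
    stop("'gamma_grid' must be strictly increasing", call. = FALSE)
  n_individuals <- assert_scalar_int(n_individuals, "n_individuals")
  reps <- assert_scalar_int(reps, "reps")
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  withr::with_seed(seed, {
    res <- lapply(gamma_grid, function(g) {
      bc <- vapply(seq_len(reps), function(i) {
        if (g == 1L) return(0)
        p <- rlnorm(g, sad_params[[1L]], sad_params[[2L]])
        p <- p / sum(p)
        xy <- rmultinom(2L, n_individuals, p)
        bray_curtis(xy[, 1L], xy[, 2L])
      }, numeric(1L))
      data.frame(gamma = g, n = n_individuals, expected_beta = mean(bc),
                 mc_se = sd(bc) / sqrt(reps))
    })
  })
  do.call(rbind, res)
}
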