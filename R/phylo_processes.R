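## betaMNTD / betaNTI / Raup-Crick and the five-way assembly-process partition.
##
## Convention for thresholds (the field's standard reading):
##   betaNTI < -2            -> homogeneous selection (HoS)
##   betaNTI > +2            -> heterogeneous selection (HeS)
##   |betaNTI| <= 2 then:
##     RC_bray < -0.95       -> homogenizing dispersal (HD)
##     RC_bray > +0.95       -> dispersal limitation (DL)
##     |RC_bray| <= 0.95     -> drift (DR)

taxa_indices <- function(x, dist_names, what) {
  supp <- names(x)[x > 0]
  if (is.null(names(x)))
    stop("count vectors must carry taxon names", call. = FALSE)
  missing <- setdiff(supp, dist_names)
  if (length(missing))
    stop(what, ": taxa missing from distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  match(supp, dist_names)
}

sample_weights <- function(x, weighted) {
  v <- x[x > 0]
  if (weighted) v / sum(v) else rep(1 / length(v), length(v))
}

#' Between-community mean nearest-taxon distance (betaMNTD)
#'
#' For each taxon present in one community, the minimum patristic distance to
#' any taxon present in the other community is found; betaMNTD is the average
#' of the two directional (abundance-weighted) means of these nearest-taxon
#' distances.
#'
#' @param x,y named non-negative count vectors with non-empty supports.
#' @param dist patristic distance matrix whose dimnames cover both supports.
#' @param weighted weight each taxon by its within-sample relative abundance
#'   (default); otherwise uniform (presence-based) weights.
#' @return non-negative betaMNTD value; 0 for identical supports.
#' @export
beta_mntd <- function(x, y, dist, weighted = TRUE) {
  if (sum(x > 0) == 0L || sum(y > 0) == 0L)
    stop("betaMNTD requires non-empty communities", call. = FALSE)
  ix <- taxa_indices(x, rownames(dist), "x")
  iy <- taxa_indices(y, rownames(dist), "y")
  cpp_bmntd_pair(dist, ix - 1L, iy - 1L,
                 sample_weights(x, weighted), sample_weights(y, weighted))
}

#' beta nearest-taxon index (betaNTI) for one sample pair
#'
#' Standardized effect size of [beta_mntd()] against a null distribution
#' obtained by shuffling taxon labels across the tips of the phylogeny
#' `n_null` times: `(obs - mean(null)) / sd(null)` with the sample (n-1)
#' standard deviation. The shuffle spans all taxa of the supplied distance
#' matrix; pass the study-level taxon set (see [process_metrics()]) rather
#' than only the pair's own taxa.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip shuffles (>= 99; default 999).
#' @param seed integer seed.
#' @return list with `beta_mntd_obs`, `beta_nti`, `null_mean`, `null_sd`,
#'   `degenerate` (TRUE when the null has zero spread, e.g. a star phylogeny;
#'   `beta_nti` is then `NA` with a warning).
#' @export
beta_nti <- function(x, y, dist, n_null = 999L, seed, weighted = TRUE) {
  n_null <- assert_scalar_int(n_null, "n_null", min = 99L)
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  ix <- taxa_indices(x, rownames(dist), "x")
  iy <- taxa_indices(y, rownames(dist), "y")
  supports <- list(ix - 1L, iy - 1L)
  weights <- list(sample_weights(x, weighted), sample_weights(y, weighted))
  G <- nrow(dist)
  obs <- cpp_bmntd_pair(dist, supports[[1L]], supports[[2L]],
                        weights[[1L]], weights[[2L]])
  perms <- withr::with_seed(seed,
    vapply(seq_len(n_null), function(i) sample.int(G), integer(G)))
  null <- cpp_bmntd_null(dist, supports, weights, perms - 1L)[, 1L]
  mu <- mean(null)
  s <- sd(null)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) warning("betaNTI null has zero spread; value undefined")
  list(beta_mntd_obs = obs,
       beta_nti = if (degenerate) NA_real_ else (obs - mu) / s,
       null_mean = mu, null_sd = s, degenerate = degenerate)
}

#' Modified Raup-Crick index on Bray-Curtis (RC_bray) for one sample pair
#'
#' Null assemblies condition on each sample's observed richness and total:
#' taxa are drawn without replacement with probability proportional to their
#' regional occurrence frequency, one individual is placed on each drawn
#' taxon, and the remaining individuals are allocated multinomially
#' proportional to the pooled relative abundances renormalized over the drawn
#' taxa. With `obs` the observed Bray-Curtis value and ties taking half
#' weight,
#' \deqn{RC_{raw} = \frac{\#\{BC_{null} < obs\} + 0.5\,\#\{BC_{null} = obs\}}{n_{null}},
#'       \quad RC_{bray} = 2 (RC_{raw} - 0.5) \in [-1, 1].}
#'
#' @param x,y named count vectors over the pool's taxa.
#' @param pool a [pool_region()] result providing `sp_freq` and
#'   `pool_rel_abund`.
#' @param n_null number of null assemblies (>= 99; default 999).
#' @param seed integer seed.
#' @return list with `bray_curtis_obs`, `rc_bray`, `rc_raw`.
#' @export
rc_bray <- function(x, y, pool, n_null = 999L, seed) {
  n_null <- assert_scalar_int(n_null, "n_null", min = 99L)
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  xs <- x[pool$taxa]; ys <- y[pool$taxa]
  if (anyNA(xs) || anyNA(ys))
    stop("count vectors must be named over the pool's taxa", call. = FALSE)
  rich <- c(sum(xs > 0), sum(ys > 0))
  tot <- c(sum(xs), sum(ys))
  if (any(rich > pool$gamma))
    stop("sample richness exceeds regional gamma", call. = FALSE)
  obs <- bray_curtis(xs, ys)
  withr::with_seed(seed, {
    null <- vapply(seq_len(n_null), function(r) {
      a <- null_sample_model_II(rich[1L], tot[1L], pool$sp_freq, pool$pool_rel_abund)
      b <- null_sample_model_II(rich[2L], tot[2L], pool$sp_freq, pool$pool_rel_abund)
      bray_curtis(a, b)
    }, numeric(1L))
  })
  rc_raw <- (sum(null < obs) + 0.5 * sum(null == obs)) / n_null
  list(bray_curtis_obs = obs, rc_bray = 2 * (rc_raw - 0.5), rc_raw = rc_raw)
}

#' Assign an assembly process from betaNTI and RC_bray
#'
#' @param beta_nti,rc_bray numeric vectors (recycled to common length).
#' @param bnti_thresh selection threshold on |betaNTI| (default 2).
#' @param rc_thresh dispersal threshold on |RC_bray| (default 0.95).
#' @return character vector over `{"HeS","HoS","HD","DL","DR"}`; `NA` where
#'   `beta_nti` is `NA`.
#' @export
classify_process <- function(beta_nti, rc_bray, bnti_thresh = 2,
                             rc_thresh = 0.95) {
  n <- max(length(beta_nti), length(rc_bray))
  beta_nti <- rep_len(beta_nti, n); rc_bray <- rep_len(rc_bray, n)
  out <- rep(NA_character_, n)
  sel_lo <- !is.na(beta_nti) & beta_nti < -bnti_thresh
  sel_hi <- !is.na(beta_nti) & beta_nti > bnti_thresh
  rest <- !is.na(beta_nti) & !sel_lo & !sel_hi
  out[sel_lo] <- "HoS"
  out[sel_hi] <- "HeS"
  out[rest & rc_bray < -rc_thresh] <- "HD"
  out[rest & rc_bray > rc_thresh] <- "DL"
  out[rest & abs(rc_bray) <= rc_thresh] <- "DR"
  out
}

#' Pairwise assembly-process metrics for one region
#'
#' Computes, for every unordered sample pair within the region: Bray-Curtis
#' dissimilarity, observed betaMNTD, betaNTI (sharing one set of `n_null` tip
#' shuffles across all pairs), RC_bray (sharing one set of `n_null`
#' whole-region null assemblies across all pairs), and the resulting process
#' label. Sharing null replicates across pairs is the standard region-level
#' formulation and is what makes 999 randomizations affordable; per-pair
#' nulls are available through [beta_nti()] and [rc_bray()].
#'
#' The betaNTI tip shuffle operates on the study-level taxon set (all taxa of
#' the table present in the phylogeny), not just the region's observed taxa:
#' selection filters the regional community out of the wider pool, so
#' restricting the shuffle to the taxa selection let through would erase the
#' very signal being tested. The Raup-Crick null, by contrast, conditions on
#' the region's observed pool (occurrence frequencies and pooled
#' abundances).
#'
#' @inheritParams region_counts
#' @param tree phylogeny (`phylo`) covering the region's taxa, or a
#'   precomputed patristic distance matrix.
#' @param n_null randomizations for both nulls (default 999).
#' @param seed integer seed.
#' @param weighted abundance-weight betaMNTD (default TRUE).
#' @param bnti_thresh,rc_thresh classification thresholds.
#' @return data.frame of class `pairwise_process_metrics`: `region`,
#'   `sample_i`, `sample_j`, `bray_curtis`, `beta_mntd_obs`, `beta_nti`,
#'   `rc_bray`, `process`.
#' @export
process_metrics <- function(table, region, tree, n_null = 999L, seed,
                            weighted = TRUE, bnti_thresh = 2,
                            rc_thresh = 0.95) {
  n_null <- assert_scalar_int(n_null, "n_null", min = 99L)
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  pool <- pool_region(table, region)
  study_taxa <- rownames(table$counts)
  d <- if (is.matrix(tree)) {
    missing <- setdiff(study_taxa, rownames(tree))
    if (length(missing))
      stop("taxa missing from distance matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    tree[study_taxa, study_taxa]
  } else patristic_distances(tree, study_taxa)
  m <- table$counts[study_taxa, region_sample_ids(table, region),
                    drop = FALSE]
  S <- ncol(m)
  G <- nrow(m)
  supports <- lapply(seq_len(S), function(s) which(m[, s] > 0) - 1L)
  weights <- lapply(seq_len(S), function(s) sample_weights(m[, s], weighted))

  ## observed betaMNTD for all pairs (identity permutation)
  obs <- cpp_bmntd_null(d, supports, weights,
                        matrix(seq_len(G) - 1L, ncol = 1L))[1L, ]
  perms <- withr::with_seed(derive_seed(seed, 1L),
    vapply(seq_len(n_null), function(i) sample.int(G), integer(G)))
  null <- cpp_bmntd_null(d, supports, weights, perms - 1L)
  nmu <- colMeans(null)
  nsd <- apply(null, 2L, sd)
  bnti <- ifelse(nsd > 0, (obs - nmu) / nsd, NA_real_)
  if (anyNA(bnti))
    warning(sum(is.na(bnti)), " pair(s) with degenerate betaNTI null")

  ## Raup-Crick: one whole-region null assembly per replicate
  bc_obs <- pairwise_bray(m)
  lt <- lower.tri(bc_obs)
  obs_bc_vec <- t(bc_obs)[lt]               # (i,j) pairs in i<j row-major order
  less <- ties <- numeric(length(obs_bc_vec))
  withr::with_seed(derive_seed(seed, 2L), {
    for (r in seq_len(n_null)) {
      nt <- null_region_table("MODEL_II", pool)
      nb <- pairwise_bray(nt)
      nb_vec <- t(nb)[lt]
      less <- less + (nb_vec < obs_bc_vec)
      ties <- ties + (nb_vec == obs_bc_vec)
    }
  })
  rc <- 2 * ((less + 0.5 * ties) / n_null - 0.5)

  idx <- which(upper.tri(bc_obs), arr.ind = TRUE)  # column-major = (i<j) pairs
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  out <- data.frame(region = region,
                    sample_i = colnames(m)[idx[, 1L]],
                    sample_j = colnames(m)[idx[, 2L]],
                    bray_curtis = obs_bc_vec,
                    beta_mntd_obs = obs,
                    beta_nti = bnti,
                    rc_bray = rc,
                    process = classify_process(bnti, rc, bnti_thresh, rc_thresh),
                    stringsAsFactors = FALSE)
  class(out) <- c("pairwise_process_metrics", "data.frame")
  out
}

#' Partition assembly processes from pairwise metrics
#'
#' Fractions of within-region sample pairs assigned to each of heterogeneous
#' selection, homogeneous selection, homogenizing dispersal, dispersal
#' limitation and drift. Pairs with undefined betaNTI are excluded (their
#' count is reported via a message) and fractions are taken over the defined
#' pairs.
#'
#' @param metrics a data.frame from [process_metrics()] (one or more regions
#'   row-bound together).
#' @return data.frame with one row per region: `region`, `n_pairs`, `HeS`,
#'   `HoS`, `HD`, `DL`, `DR` (fractions summing to 1).
#' @export
partition_processes <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1L)
  levs <- c("HeS", "HoS", "HD", "DL", "DR")
  do.call(rbind, lapply(split(metrics, metrics$region), function(g) {
    drop <- is.na(g$process)
    if (any(drop))
      message(sum(drop), " pair(s) with undefined betaNTI excluded in region ",
              g$region[1L])
    g <- g[!drop, , drop = FALSE]
    if (!nrow(g)) stop("no classifiable pairs in region ", g$region[1L],
                       call. = FALSE)
    fr <- as.numeric(table(factor(g$process, levels = levs))) / nrow(g)
    cbind(data.frame(region = g$region[1L], n_pairs = nrow(g),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(fr, levs))))
  }))
}
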