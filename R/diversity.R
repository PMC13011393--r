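#' Bray-Curtis dissimilarity between two count vectors
#'
#' \deqn{BC(x, y) = \frac{\sum_i |x_i - y_i|}{\sum_i (x_i + y_i)}}
#'
#' Computed on (rarefied) counts directly; with equal sample depths this is
#' identical to the relative-abundance form.
#'
#' @param x,y non-negative numeric vectors of equal length, not both all-zero.
#' @return dissimilarity in \[0, 1\]; 0 iff `x == y`, 1 for disjoint supports.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined: both vectors are all-zero",
                     call. = FALSE)
  sum(abs(x - y)) / tot
}

## All unordered-pair Bray-Curtis values for a taxa x samples matrix.
## Manhattan distances and column totals give the whole matrix in one pass.
pairwise_bray <- function(m) {
  manh <- as.matrix(dist(t(m), method = "manhattan"))
  tot <- colSums(m)
  manh / outer(tot, tot, "+")
}

mean_pairwise_bray <- function(m) {
  bc <- pairwise_bray(m)
  mean(bc[lower.tri(bc)])
}

#' Observed richness of one sample
#' @param x count vector (one sample column).
#' @return number of taxa with count > 0.
#' @export
alpha_richness <- function(x) sum(x > 0)

#' Alpha, beta and gamma diversity of one region
#'
#' Alpha is per-sample observed richness; beta is the mean pairwise
#' Bray-Curtis dissimilarity among the region's samples; gamma is the pooled
#' richness of the region.
#'
#' @inheritParams region_counts
#' @return an object of class `regional_diversity`: list with `region`,
#'   `alpha` (named integer), `beta_pairs` (data.frame `sample_i`, `sample_j`,
#'   `bray_curtis` over all unordered pairs), `beta_mean`, `gamma`.
#' @export
regional_diversity <- function(table, region) {
  m <- region_counts(table, region)
  if (ncol(m) < 2L) stop("region '", region, "' has fewer than 2 samples",
                         call. = FALSE)
  bc <- pairwise_bray(m)
  idx <- which(lower.tri(bc), arr.ind = TRUE)
  pairs <- data.frame(sample_i = colnames(m)[idx[, 2L]],
                      sample_j = colnames(m)[idx[, 1L]],
                      bray_curtis = bc[idx],
                      stringsAsFactors = FALSE)
  structure(list(region = region,
                 alpha = colSums(m > 0L),
                 beta_pairs = pairs,
                 beta_mean = mean(pairs$bray_curtis),
                 gamma = pool_region(table, region)$gamma),
            class = "regional_diversity")
}

#' @export
print.regional_diversity <- function(x, ...) {
  cat(sprintf("region '%s': gamma = %d, mean alpha = %.1f, mean pairwise BC = %.4f (%d pairs)\n",
              x$region, x$gamma, mean(x$alpha), x$beta_mean, nrow(x$beta_pairs)))
  invisible(x)
}

#' Per-region diversity summary for a whole table
#' @inheritParams regions
#' @return data.frame with one row per region: `region`, `n_samples`, `gamma`,
#'   `alpha_mean`, `beta_mean`.
#' @export
diversity_summary <- function(table) {
  do.call(rbind, lapply(regions(table), function(r) {
    d <- regional_diversity(table, r)
    data.frame(region = r, n_samples = length(d$alpha), gamma = d$gamma,
               alpha_mean = mean(d$alpha), beta_mean = d$beta_mean,
               stringsAsFactors = FALSE)
  }))
}
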