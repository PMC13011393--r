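#' Standardize environmental variables (z-scores)
#'
#' Mean-centres and scales each variable to unit sample (n-1) standard
#' deviation, removing the effect of measurement magnitude before distances
#' or ordination.
#'
#' @param env numeric matrix, samples x variables, with dimnames.
#' @return matrix of the same shape with per-variable mean 0 and sd 1.
#' @export
standardize_env <- function(env) {
  if (!is.matrix(env) || !is.numeric(env))
    stop("'env' must be a numeric matrix", call. = FALSE)
  sds <- apply(env, 2L, sd)
  const <- !is.finite(sds) | sds == 0
  if (any(const))
    stop("constant environmental variable(s): ",
         paste(colnames(env)[const], collapse = ", "), call. = FALSE)
  scale(env, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Environmental heterogeneity: Euclidean distance on standardized variables
#' @param env_z standardized environmental matrix (see [standardize_env()]).
#' @return a `dist` object over samples.
#' @export
env_distance <- function(env_z) dist(env_z, method = "euclidean")

dist_labels <- function(d) attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))

#' Association between community dissimilarity and environmental heterogeneity
#'
#' Ordinary least squares of the pairwise community dissimilarities on the
#' pairwise environmental distances, with significance assessed by a
#' Mantel-style permutation of sample labels (pairwise values are not
#' independent, so the OLS p-value would be anticonservative). The permuted
#' statistic is the Pearson correlation; the test is two-sided.
#'
#' @param beta_d community dissimilarities (`dist` or square matrix).
#' @param env_d environmental distances over the same samples, same order.
#' @param n_perm label permutations (default 999).
#' @param seed integer seed.
#' @return list: `slope`, `intercept`, `r`, `p_value`, `n_pairs`, `n_perm`.
#' @export
beta_env_association <- function(beta_d, env_d, n_perm = 999L, seed) {
  n_perm <- assert_scalar_int(n_perm, "n_perm")
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  bm <- as.matrix(beta_d); em <- as.matrix(env_d)
  if (!identical(dim(bm), dim(em)))
    stop("dissimilarity matrices differ in size", call. = FALSE)
  n <- nrow(bm)
  lt <- lower.tri(bm)
  y <- bm[lt]; x <- em[lt]
  if (length(y) < 3L) stop("fewer than 3 sample pairs", call. = FALSE)
  vx <- stats::var(x)
  slope <- if (vx > 0) stats::cov(x, y) / vx else 0
  intercept <- mean(y) - slope * mean(x)
  degenerate <- vx == 0 || stats::var(y) == 0
  r_obs <- if (degenerate) 0 else stats::cor(x, y)
  p_value <- if (degenerate) 1 else {
    hits <- withr::with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        rp <- stats::cor(em[p, p][lt], y)
        !is.na(rp) && abs(rp) >= abs(r_obs)
      }, logical(1L)))
    })
    (hits + 1) / (n_perm + 1)
  }
  list(slope = slope, intercept = intercept, r = r_obs, p_value = p_value,
       n_pairs = length(y), n_perm = n_perm)
}

## Principal-coordinates embedding of a dissimilarity matrix: double-centre
## -0.5 * J D^2 J, eigendecompose, keep positive axes. Optional Lingoes
## correction adds the smallest constant to all squared off-diagonal
## dissimilarities that makes the configuration Euclidean.
pcoa_embed <- function(d, correction = c("none", "lingoes"), tol = 1e-8) {
  correction <- match.arg(correction)
  D <- as.matrix(d)
  n <- nrow(D)
  center <- function(D2) {
    J <- diag(n) - matrix(1 / n, n, n)
    -0.5 * J %*% D2 %*% J
  }
  e <- eigen(center(D ^ 2), symmetric = TRUE)
  if (correction == "lingoes" && min(e$values) < -tol) {
    c_add <- -min(e$values)
    D2 <- D ^ 2 + 2 * c_add
    diag(D2) <- 0
    e <- eigen(center(D2), symmetric = TRUE)
  }
  scale_tol <- tol * max(abs(e$values))
  keep <- e$values > scale_tol
  neg <- sum(abs(e$values[e$values < -scale_tol]))
  Y <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                nrow = sum(keep))
  rownames(Y) <- rownames(D)
  list(coords = Y, eigenvalues = e$values, negative_inertia = neg)
}

#' Distance-based redundancy analysis (db-RDA)
#'
#' Constrained ordination of a community dissimilarity matrix on
#' environmental variables, built from its definition: the dissimilarities
#' are embedded by principal-coordinates analysis (axes with positive
#' eigenvalues retained; negative eigenvalues are dropped and their summed
#' magnitude reported, or removed by the Lingoes correction), and the
#' coordinates are regressed on the standardized variables. The constrained
#' proportion is
#' \deqn{R^2 = \frac{\|H Y\|_F^2}{\|Y\|_F^2}}
#' with `H` the hat matrix of the (centred) environmental predictors. The
#' global test permutes sample rows; marginal per-variable tests permute
#' residuals under the reduced model omitting that variable.
#'
#' @param d community dissimilarities (`dist` or square symmetric matrix).
#' @param env_z standardized environmental matrix, rows aligned with `d`.
#' @param n_perm permutations for the tests (default 999).
#' @param seed integer seed.
#' @param correction `"none"` (drop negative axes) or `"lingoes"`.
#' @return object of class `dbrda_result`: `total_inertia`,
#'   `constrained_inertia`, `r_squared`, `global_F`, `global_p`, `terms`
#'   (data.frame `variable`, `F`, `p_value`), `negative_inertia`, `n_perm`.
#' @export
dbrda <- function(d, env_z, n_perm = 999L, seed, correction = "none") {
  n_perm <- assert_scalar_int(n_perm, "n_perm")
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  emb <- pcoa_embed(d, correction)
  Y <- emb$coords
  n <- nrow(Y)
  if (!is.matrix(env_z) || nrow(env_z) != n)
    stop("'env_z' rows must match the dissimilarity matrix", call. = FALSE)
  X <- scale(env_z, center = TRUE, scale = FALSE)
  p <- ncol(X)
  if (p > n - 1L)
    stop("more environmental variables than samples - 1", call. = FALSE)

  hat <- function(Xm) {
    q <- qr(Xm)
    function(Ym) qr.fitted(q, Ym)
  }
  fit_full <- hat(X)
  ss <- function(M) sum(M ^ 2)
  ## all sums of squares via projections (non-negative by construction, so an
  ## exact fit cannot produce a negative residual through cancellation)
  f_ratio <- function(num, den) {
    if (den <= 0) return(if (num > 0) Inf else 0)
    num / den
  }
  total <- ss(Y)                        # Y is centred by construction
  Yhat <- fit_full(Y)
  constrained <- ss(Yhat)
  resid_full <- ss(Y - Yhat)
  df_res <- n - p - 1L
  F_obs <- f_ratio(constrained / p, resid_full / df_res)

  ## global test: unrestricted permutation of sample rows
  global_hits <- withr::with_seed(derive_seed(seed, 1L), {
    sum(vapply(seq_len(n_perm), function(i) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      Yph <- fit_full(Yp)
      Fp <- f_ratio(ss(Yph) / p, ss(Yp - Yph) / df_res)
      Fp >= F_obs
    }, logical(1L)))
  })

  ## marginal tests: residual permutation under the reduced model
  terms <- do.call(rbind, lapply(seq_len(p), function(k) {
    Xr <- X[, -k, drop = FALSE]
    fit_red <- if (ncol(Xr)) hat(Xr) else function(Ym) 0 * Ym
    fitted_red <- fit_red(Y)
    E <- Y - fitted_red
    F_k <- f_ratio(ss(Yhat - fitted_red), resid_full / df_res)
    hits <- withr::with_seed(derive_seed(seed, 100L + k), {
      sum(vapply(seq_len(n_perm), function(i) {
        Ystar <- fitted_red + E[sample.int(n), , drop = FALSE]
        full_s <- fit_full(Ystar)
        Fs <- f_ratio(ss(full_s - fit_red(Ystar)),
                      ss(Ystar - full_s) / df_res)
        Fs >= F_k
      }, logical(1L)))
    })
    data.frame(variable = colnames(env_z)[k] %||% paste0("V", k), F = F_k,
               p_value = (hits + 1) / (n_perm + 1), stringsAsFactors = FALSE)
  }))

  structure(list(total_inertia = total, constrained_inertia = constrained,
                 r_squared = constrained / total, global_F = F_obs,
                 global_p = (global_hits + 1) / (n_perm + 1), terms = terms,
                 negative_inertia = emb$negative_inertia, n_perm = n_perm),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("db-RDA: R2 = %.3f (constrained %.3f / total %.3f), global F = %.2f, p = %.4f\n",
              x$r_squared, x$constrained_inertia, x$total_inertia,
              x$global_F, x$global_p))
  if (x$negative_inertia > 0)
    cat(sprintf("  negative inertia dropped: %.4f\n", x$negative_inertia))
  print(x$terms, row.names = FALSE)
  invisible(x)
}
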