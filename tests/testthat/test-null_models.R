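test_that("beta-deviation implements the standardized effect size exactly", {
  ens <- structure(list(region = "R", scheme = "MODEL_I", n_perm = 3L,
                        null_beta_means = c(0.2, 0.4, 0.6),
                        null_tables = list(), seed = 1L),
                   class = "null_ensemble")
  dev <- beta_deviation(0.8, ens)
  expect_equal(dev$null_mean, 0.4)
  expect_equal(dev$null_sd, 0.2)
  expect_equal(dev$ses, 2.0)
  expect_equal(beta_deviation(0.4, ens)$ses, 0)
  expect_equal(beta_deviation(0.6, ens)$ses, 1)  # one sample-sd above the mean

  ens$null_beta_means <- rep(0.5, 3)
  expect_warning(dz <- beta_deviation(0.7, ens), "zero spread")
  expect_true(dz$degenerate)
  expect_true(is.na(dz$ses))
})

test_that("deviation labels follow the sign rule", {
  expect_identical(interpret_deviation(2.0), "HeS/DL")
  expect_identical(interpret_deviation(-3.1), "HoS/HD")
  expect_identical(interpret_deviation(0), "drift")
  expect_identical(interpret_deviation(0.04), "drift")
  expect_identical(interpret_deviation(-0.06), "HoS/HD")
  expect_error(interpret_deviation(NA_real_), "finite")
})

test_that("null tables conserve per-sample richness, totals and value multisets", {
  tab <- neutral_region(50, 6, 300, seed = 3)
  obs <- region_counts(tab, "R1", drop_empty_taxa = TRUE)
  for (fun in list(null_model_I, null_model_II)) {
    ens <- fun(tab, "R1", n_perm = 25, seed = 11, keep_tables = TRUE)
    for (nt in ens$null_tables) {
      expect_identical(colSums(nt > 0), colSums(obs > 0))
      expect_identical(colSums(nt), colSums(obs))
    }
    expect_length(ens$null_beta_means, 25)
  }
  # MODEL_I additionally conserves each sample's abundance-value multiset
  ens1 <- null_model_I(tab, "R1", n_perm = 10, seed = 5, keep_tables = TRUE)
  for (nt in ens1$null_tables)
    for (s in seq_len(ncol(obs)))
      expect_equal(sort(nt[nt[, s] > 0, s]), sort(obs[obs[, s] > 0, s]),
                   ignore_attr = TRUE)
})

test_that("saturated and degenerate regions behave as forced", {
  # every sample contains all gamma taxa: null support is forced
  m <- matrix(c(3L, 1L, 2L, 5L, 2L, 1L, 4L, 4L, 1L), 3, 3)
  tab <- make_table(m)
  ens <- null_model_I(tab, "R1", n_perm = 15, seed = 2, keep_tables = TRUE)
  for (nt in ens$null_tables) expect_true(all(nt > 0))

  # gamma = 1: every null table equals the observed table; sd = 0 flagged
  m1 <- matrix(c(5L, 3L), 1, 2)
  tab1 <- make_table(m1)
  ens1 <- null_model_II(tab1, "R1", n_perm = 10, seed = 2, keep_tables = TRUE)
  for (nt in ens1$null_tables) expect_equal(unname(nt), unname(m1))
  expect_warning(d <- beta_deviation(ens1$null_beta_means[1], ens1),
                 "zero spread")
  expect_true(d$degenerate)
})

test_that("MODEL_I taxon draws have the hypergeometric overlap expectation", {
  # regional gamma 10 (two extra samples keep all taxa in the pool); the two
  # focal samples have richness 3 each: E[shared] = 3 * 3 / 10
  m <- matrix(0L, 10, 4)
  m[1:3, 1] <- c(5L, 4L, 1L); m[1:3, 2] <- c(2L, 2L, 6L)
  m[1:5, 3] <- 1L; m[6:10, 4] <- 1L
  tab <- make_table(m)
  expect_identical(pool_region(tab, "R1")$gamma, 10L)
  ens <- null_model_I(tab, "R1", n_perm = 4000, seed = 8, keep_tables = TRUE)
  shared <- vapply(ens$null_tables,
                   function(nt) sum(nt[, 1] > 0 & nt[, 2] > 0), numeric(1))
  se <- sqrt(3 * 0.3 * 0.7 * 7 / 9) / sqrt(4000)
  expect_lt(abs(mean(shared) - 0.9), 4 * se)
})

test_that("MODEL_II selection matches sequential weighted sampling without replacement", {
  # enumeration oracle over ordered draws for 4 taxa, richness 2
  w <- c(4, 2, 1, 1)
  subsets <- combn(4, 2)
  p_subset <- apply(subsets, 2, function(ij) {
    i <- ij[1]; j <- ij[2]; W <- sum(w)
    w[i] / W * w[j] / (W - w[i]) + w[j] / W * w[i] / (W - w[j])
  })
  names(p_subset) <- apply(subsets, 2, paste, collapse = "-")
  draws <- withr::with_seed(31, replicate(6000, {
    v <- betanull:::null_sample_model_II(2, 10, w, rep(0.25, 4))
    paste(which(v > 0), collapse = "-")
  }))
  freq <- table(factor(draws, levels = names(p_subset))) / length(draws)
  expect_lt(max(abs(as.numeric(freq) - p_subset)), 0.025)
})

test_that("with a flat pool MODEL_II reduces to uniform draws with multinomial fill", {
  # columns are rotations of (0, 9, 13, 18): equal sp_freq (6) and exactly
  # equal pooled abundance (0.25) for all four taxa, richness 3 per sample
  vals <- c(0L, 9L, 13L, 18L)
  m <- vapply(0:7, function(k) vals[(seq_len(4) + k - 1) %% 4 + 1], integer(4))
  tab <- make_table(m)
  e2 <- null_model_II(tab, "R1", n_perm = 1000, seed = 2)
  # independent reference: uniform subset draw + one-each multinomial fill
  ref <- withr::with_seed(77, replicate(1000, {
    nt <- vapply(seq_len(8), function(s) {
      out <- numeric(4)
      idx <- sample.int(4, 3)
      out[idx] <- 1 + rmultinom(1, 40 - 3, rep(1 / 3, 3))[, 1]
      out
    }, numeric(4))
    betanull:::mean_pairwise_bray(nt)
  }))
  ks <- suppressWarnings(stats::ks.test(e2$null_beta_means, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("ses is stable under taxon relabelling and sample reordering", {
  tab <- neutral_region(40, 8, 400, seed = 21)
  beta_obs <- regional_diversity(tab, "R1")$beta_mean
  ses0 <- beta_deviation(beta_obs, null_model_I(tab, "R1", 2000, seed = 3))$ses
  perm_t <- withr::with_seed(1, sample(nrow(tab$counts)))
  perm_s <- withr::with_seed(2, sample(ncol(tab$counts)))
  tab2 <- community_table(tab$counts[perm_t, perm_s], tab$sample_region[perm_s])
  ses1 <- beta_deviation(regional_diversity(tab2, "R1")$beta_mean,
                         null_model_I(tab2, "R1", 2000, seed = 3))$ses
  expect_equal(beta_obs, regional_diversity(tab2, "R1")$beta_mean)
  # only Monte-Carlo noise remains; its scale grows with |ses|
  expect_lt(abs(ses0 - ses1), 0.05 * abs(ses0) + 0.2)
})

test_that("expected beta-gamma curve behaves over its grid", {
  curve <- expected_beta_gamma(c(1L, 10L, 100L), 500L, reps = 150L, seed = 4)
  expect_identical(nrow(curve), 3L)
  expect_equal(curve$expected_beta[1], 0)
  expect_true(all(curve$expected_beta >= 0 & curve$expected_beta <= 1))
  expect_error(expected_beta_gamma(c(10L, 5L), 100L, seed = 1), "increasing")
})
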