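test_that("betaMNTD matches hand values and is a symmetric non-negative measure", {
  d <- toy_dist3()
  expect_equal(beta_mntd(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 0), d,
                         weighted = FALSE), 2)
  # identical communities: every taxon finds itself
  x <- c(A = 2, B = 1, C = 4)
  expect_equal(beta_mntd(x, x, d), 0)
  withr::with_seed(14, {
    tr <- ape::rphylo(12, 1, 0)
    dd <- ape::cophenetic.phylo(tr)
    for (i in 1:10) {
      x <- stats::setNames(rpois(12, 1) + c(1, rep(0, 11)), rownames(dd))
      y <- stats::setNames(rpois(12, 1) + c(rep(0, 11), 1), rownames(dd))
      expect_identical(beta_mntd(x, y, dd), beta_mntd(y, x, dd))
      expect_gte(beta_mntd(x, y, dd), 0)
    }
  })
  expect_error(beta_mntd(c(A = 1, Z = 2), c(A = 1), d), "Z")
  expect_error(beta_mntd(c(A = 0), c(A = 1), d), "non-empty")
})

test_that("betaNTI is flagged degenerate on a star phylogeny", {
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  d <- ape::cophenetic.phylo(star)
  x <- stats::setNames(c(3, 1, 0, 0, 2, 0), rownames(d))
  y <- stats::setNames(c(0, 0, 2, 5, 0, 1), rownames(d))
  expect_warning(res <- beta_nti(x, y, d, n_null = 99, seed = 1),
                 "zero spread")
  expect_true(res$degenerate)
  expect_true(is.na(res$beta_nti))
})

test_that("RC_bray hits its boundaries for extreme observations", {
  tab <- neutral_region(20, 4, 200, seed = 5)
  pool <- pool_region(tab, "R1")
  taxa <- pool$taxa
  # identical samples: observed BC = 0, below every null draw
  x <- stats::setNames(tab$counts[taxa, 1], taxa)
  low <- rc_bray(x, x, pool, n_null = 199, seed = 2)
  expect_equal(low$rc_bray, -1)
  # saturated 3-taxon pool with extreme abundance reversal: the null fill is
  # pool-proportional, so every null BC sits far below the observed 0.97
  m <- matrix(c(98L, 1L, 1L, 1L, 1L, 98L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tab3 <- community_table(m, stats::setNames(rep("R1", 2), colnames(m)))
  pool3 <- pool_region(tab3, "R1")
  hi <- rc_bray(c(a = 98, b = 1, c = 1), c(a = 1, b = 1, c = 98), pool3,
                n_null = 199, seed = 3)
  expect_equal(hi$bray_curtis_obs, 194 / 200)
  expect_equal(hi$rc_bray, 1)
  expect_true(low$rc_bray >= -1 && hi$rc_bray <= 1)
})

test_that("threshold classification is correct, exhaustive and exclusive", {
  expect_identical(classify_process(-3, 0), "HoS")
  expect_identical(classify_process(3, 0), "HeS")
  expect_identical(classify_process(1, 0.99), "DL")
  expect_identical(classify_process(-1, -0.99), "HD")
  expect_identical(classify_process(0, 0), "DR")
  expect_identical(classify_process(2, 0.95), "DR")     # boundaries inclusive
  expect_identical(classify_process(NA, 0.5), NA_character_)
  withr::with_seed(8, {
    lab <- classify_process(runif(500, -5, 5), runif(500, -1, 1))
    expect_false(anyNA(lab))
    expect_true(all(lab %in% c("HeS", "HoS", "HD", "DL", "DR")))
  })
})

test_that("process partitions count labels and always sum to one", {
  mk <- function(bnti, rc) data.frame(region = "R", sample_i = "a",
                                      sample_j = "b", bray_curtis = 0.5,
                                      beta_mntd_obs = 1, beta_nti = bnti,
                                      rc_bray = rc,
                                      process = classify_process(bnti, rc))
  all_hos <- do.call(rbind, replicate(4, mk(-3, 0), simplify = FALSE))
  p <- partition_processes(all_hos)
  expect_equal(p$HoS, 1)
  expect_equal(p$HeS + p$HD + p$DL + p$DR, 0)

  mixed <- rbind(mk(3, 0), mk(-3, 0), mk(0, 0), mk(0, 0.2))
  p2 <- partition_processes(mixed)
  expect_equal(unlist(p2[c("HeS", "HoS", "DR", "HD", "DL")]),
               c(HeS = .25, HoS = .25, DR = .5, HD = 0, DL = 0))

  # undefined betaNTI rows are excluded with a message
  withna <- rbind(mk(NA, 0), mk(-3, 0))
  expect_message(p3 <- partition_processes(withna), "excluded")
  expect_equal(p3$HoS, 1)
  expect_identical(p3$n_pairs, 2L - 1L)
})

test_that("region-level metrics are internally consistent and deterministic", {
  sc <- simulate_scenario("DR", gamma = 60L, n_samples = 5L, depth = 400L,
                          seed = 9)
  met <- process_metrics(sc$table, regions(sc$table), sc$tree, n_null = 99,
                         seed = 4)
  expect_identical(nrow(met), 10L)
  expect_true(all(met$rc_bray >= -1 & met$rc_bray <= 1))
  d <- regional_diversity(sc$table, regions(sc$table))
  expect_equal(sort(met$bray_curtis), sort(d$beta_pairs$bray_curtis))
  # same seed, same answer
  met2 <- process_metrics(sc$table, regions(sc$table), sc$tree, n_null = 99,
                          seed = 4)
  expect_identical(met, met2)
  # pairwise beta_mntd agrees with the standalone function
  taxa <- rownames(sc$table$counts)
  dmat <- patristic_distances(sc$tree, taxa)
  x <- stats::setNames(sc$table$counts[, met$sample_i[1]], taxa)
  y <- stats::setNames(sc$table$counts[, met$sample_j[1]], taxa)
  expect_equal(met$beta_mntd_obs[1], beta_mntd(x, y, dmat))
  # fractions over one region sum to 1
  expect_equal(sum(unlist(partition_processes(met)[c("HeS", "HoS", "HD", "DL", "DR")])), 1,
               tolerance = 1e-9)
})
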