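test_that("community tables round-trip through TSV with metadata", {
  m <- matrix(c(1L, 0L, 5L, 2L, 3L, 0L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tab <- community_table(m, c(s1 = "R1", s2 = "R1"), c(s1 = 21, s2 = 21.5))
  tf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  write_community_table(tab, tf, mf)
  back <- read_community_table(tf, mf)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$sample_region, tab$sample_region)
  expect_equal(back$latitude, tab$latitude)
})

test_that("loader rejects malformed tables with informative errors", {
  tf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tregion", "s1\tR1", "s2\tR1"), mf)

  writeLines(c("taxon_id\ts1\ts2", "a\t1\t2", "b\t-1\t3"), tf)
  expect_error(read_community_table(tf, mf), "b")

  writeLines(c("taxon_id\ts1\ts2", "a\t1\t2", "b\t0.5\t3"), tf)
  expect_error(read_community_table(tf, mf), "non-integer|invalid")

  writeLines(c("taxon_id\ts1\ts2\ts3", "a\t1\t2\t4"), tf)
  expect_error(read_community_table(tf, mf), "s3")

  expect_error(make_table(matrix(c(1L, 0L, 0L, 0L), 2, 2)), "all-zero")
  m <- matrix(1L, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(community_table(m, c(s1 = "R", s2 = "R")), "duplicate")
})

test_that("rarefaction conserves depth and never exceeds original counts", {
  tab <- neutral_region(40, 6, 800, seed = 2)
  for (seed in c(1, 99)) {
    r <- rarefy(tab, 300, seed = seed)
    expect_true(all(colSums(r$counts) == 300))
    expect_true(all(r$counts <= tab$counts))
  }
  # depth equal to the total reproduces the column exactly
  m <- matrix(c(4L, 6L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  m2 <- cbind(m, s2 = c(7L, 9L)); colnames(m2) <- c("s1", "s2")
  tab2 <- make_table(m2)
  expect_identical(rarefy(tab2, 10, seed = 1)$counts[, "s1"], m[, 1])
  # reproducibility and sensitivity to the seed
  expect_identical(rarefy(tab, 300, seed = 7)$counts,
                   rarefy(tab, 300, seed = 7)$counts)
  # shallow samples: error naming the sample, or dropped under the flag
  expect_error(rarefy(tab2, 12, seed = 1), "s1")
  expect_warning(dropped <- rarefy(tab2, 12, seed = 1, drop_shallow = TRUE),
                 "s1")
  expect_identical(colnames(dropped$counts), "s2")
})

test_that("rarefied counts follow the hypergeometric expectation", {
  m <- matrix(c(1000L, 1000L), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  tab <- make_table(m)
  draws <- vapply(1:200, function(s) rarefy(tab, 200, seed = s)$counts[1, 1],
                  integer(1))
  se <- sqrt(200 * 0.5 * 0.5 * (2000 - 200) / (2000 - 1)) / sqrt(200)
  expect_lt(abs(mean(draws) - 100), 3 * se)
})

test_that("regional pools summarize gamma, occurrence and pooled abundance", {
  m <- matrix(c(2L, 0L, 1L, 0L, 0L, 3L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  pl <- pool_region(make_table(m), "R1")
  expect_identical(pl$gamma, 2L)
  expect_equal(pl$sp_freq, c(a = 1, c = 2))
  expect_equal(pl$pool_rel_abund, c(a = 2 / 6, c = 4 / 6))
  expect_equal(pl$samp_rich, c(s01 = 2, s02 = 1), ignore_attr = TRUE)
  expect_equal(sum(pl$pool_rel_abund), 1, tolerance = 1e-9)

  # disjoint supports: gamma is the union
  m2 <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  expect_identical(pool_region(make_table(m2), "R1")$gamma, 2L)
  expect_equal(pool_region(make_table(m2), "R1")$sp_freq,
               c(1, 1), ignore_attr = TRUE)
  # single shared taxon normalizes to 1
  m3 <- matrix(c(5L, 3L), 1, 2)
  expect_equal(pool_region(make_table(m3), "R1")$pool_rel_abund, 1,
               ignore_attr = TRUE)
  expect_error(pool_region(make_table(m), "nope"), "unknown region")
})

test_that("pooled gamma equals the richness of the summed region subtable", {
  for (seed in 1:5) {
    tab <- neutral_region(60, 5, 300, seed = seed)
    pl <- pool_region(tab, "R1")
    expect_identical(pl$gamma, sum(rowSums(region_counts(tab, "R1")) > 0))
    expect_true(all(pl$samp_rich <= pl$gamma))
    expect_true(all(pl$sp_freq >= 1 & pl$sp_freq <= pl$n_samples))
  }
})

test_that("environmental and phylogeny loaders validate their inputs", {
  ef <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tpH\ttemp", "s1\t7.1\t12", "s2\t8.0\t15"), ef)
  env <- read_env_table(ef)
  expect_equal(dim(env), c(2, 2))
  expect_equal(env["s2", "pH"], 8.0)

  writeLines(c("sample\tpH\ttemp", "s1\t7.1\tNA", "s2\t8.0\t15"), ef)
  expect_error(read_env_table(ef), "missing")
  imp <- read_env_table(ef, impute = TRUE)
  expect_equal(imp["s1", "temp"], 15)

  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):0.5,C:1.5);", tf)
  tree <- read_phylogeny(tf)
  d <- patristic_distances(tree)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 3)
  expect_true(isSymmetric(d))
  expect_error(patristic_distances(tree, c("A", "Z")), "Z")
})
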