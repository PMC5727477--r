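test_that("tip shuffling relabels without changing the distance multiset", {
  tr <- simulate_tree(10, 1, rng_seed = 1)
  d <- patristic_distances(tr)
  expect_identical(shuffle_tips(d, perm = 1:10), d)
  set.seed(2)
  ds <- shuffle_tips(d)
  expect_identical(dimnames(ds), dimnames(d))
  expect_equal(sort(ds[upper.tri(ds)]), sort(d[upper.tri(d)]))
})

test_that("permutation-invariant communities yield undefined deviations", {
  tr <- simulate_tree(8, 1, rng_seed = 3)
  d <- patristic_distances(tr)
  cm <- matrix(1, 8, 2, dimnames = list(tr$tip.label, c("a", "b")))
  res <- suppressMessages(beta_nti(cm, d, n_null = 99, rng_seed = 4))
  expect_true(is.na(res$deviation["a", "b"]))
  expect_equal(res$n_undefined, 1L)
})

test_that("Bray-Curtis evaluates its defining formula", {
  x <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2,
              dimnames = list(c("A", "B", "C"), c("j", "k")))
  expect_equal(bray_curtis(x)["j", "k"], 0.5)
  expect_equal(bray_curtis(cbind(x, j2 = x[, "j"]))["j", "j2"], 0)
  y <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("A", "B"), c("j", "k")))
  expect_equal(bray_curtis(y)["j", "k"], 1)
  x[1, 1] <- -1
  expect_error(bray_curtis(x), "negative")
})

test_that("RC-bray hits its analytic extremes", {
  tr <- simulate_tree(30, 1, rng_seed = 11)
  cm <- random_cm(tr, 6, seed = 12)
  # identical communities: observed BC = 0 is never beaten
  cm2 <- cbind(cm, dup = cm[, 1])
  rc <- raup_crick_bray(cm2, n_null = 199, rng_seed = 13)
  expect_lte(rc$rc["s01", "dup"], -0.95)

  # disjoint supports drawn from a shared high-overlap pool
  cm3 <- cm
  cm3[16:30, 1] <- 0; cm3[1:15, 2] <- 0   # s01, s02 disjoint
  cm3[, 3:6] <- cm[, 3:6]                 # context: full-support samples
  rc3 <- raup_crick_bray(cm3, n_null = 199, rng_seed = 14)
  expect_gte(rc3$rc["s01", "s02"], 0.95)

  expect_true(all(rc$rc[upper.tri(rc$rc)] >= -1 &
                    rc$rc[upper.tri(rc$rc)] <= 1))
})

test_that("RC-bray validates its inputs", {
  tr <- simulate_tree(10, 1, rng_seed = 21)
  cm <- random_cm(tr, 3, seed = 22)
  expect_error(raup_crick_bray(cm * 1.5, n_null = 99), "integer")
  # richness larger than the pool universe
  stats <- rc_pool_stats(cm[1:3, , drop = FALSE] + 1)
  expect_error(rc_null_communities(stats, richness = 5, totals = 10),
               "richness|pool")
})

test_that("null draws preserve richness and totals", {
  tr <- simulate_tree(25, 1, rng_seed = 31)
  cm <- random_cm(tr, 5, seed = 32)
  stats <- rc_pool_stats(cm)
  nc <- rc_null_communities(stats, richness = c(5, 10), totals = c(40, 80),
                            rng_seed = 33)
  expect_equal(unname(colSums(nc > 0)), c(5, 10))
  expect_equal(unname(colSums(nc)), c(40, 80))
})

test_that("deviations are invariant to uniform branch-length rescaling", {
  tr <- simulate_tree(20, 1, rng_seed = 41)
  cm <- random_cm(tr, 5, seed = 42)
  d <- patristic_distances(tr)
  a <- beta_nti(cm, d, n_null = 199, rng_seed = 43)
  b <- beta_nti(cm, d * 37.5, n_null = 199, rng_seed = 43)
  expect_lt(max(abs(a$deviation - b$deviation), na.rm = TRUE), 1e-8)
  a2 <- beta_nri(cm, d, n_null = 199, rng_seed = 44)
  b2 <- beta_nri(cm, d * 0.01, n_null = 199, rng_seed = 44)
  expect_lt(max(abs(a2$deviation - b2$deviation), na.rm = TRUE), 1e-8)
})

test_that("deviation matrices are symmetric and seeded runs reproduce", {
  tr <- simulate_tree(15, 1, rng_seed = 51)
  cm <- random_cm(tr, 4, seed = 52)
  d <- patristic_distances(tr)
  r1 <- beta_nti(cm, d, n_null = 99, rng_seed = 53)
  r2 <- beta_nti(cm, d, n_null = 99, rng_seed = 53)
  expect_identical(r1$deviation, r2$deviation)
  expect_identical(r1$deviation, t(r1$deviation))
  rc1 <- raup_crick_bray(cm, n_null = 99, rng_seed = 54)
  rc2 <- raup_crick_bray(cm, n_null = 99, rng_seed = 54)
  expect_identical(rc1$rc, rc2$rc)
})

test_that("the pool argument scopes samples and the shuffle universe", {
  tr <- simulate_tree(20, 1, rng_seed = 61)
  cm <- random_cm(tr, 6, seed = 62)
  sub <- colnames(cm)[1:3]
  r <- beta_nti(cm, patristic_distances(tr), n_null = 99, rng_seed = 63,
                pool = sub)
  expect_equal(rownames(r$deviation), sub)
  expect_error(beta_nti(cm, patristic_distances(tr), n_null = 99,
                        pool = c("s01", "nope")), "not in community")
})

test_that("pair_table flattens results to long format", {
  tr <- simulate_tree(10, 1, rng_seed = 71)
  cm <- random_cm(tr, 4, seed = 72)
  d <- patristic_distances(tr)
  b <- beta_nti(cm, d, n_null = 99, rng_seed = 73)
  tab <- pair_table(b)
  expect_equal(nrow(tab), choose(4, 2))
  expect_named(tab, c("sample_i", "sample_j", "metric", "obs", "null_mean",
                      "null_sd", "deviation"))
  expect_equal(tab$deviation[tab$sample_i == "s01" & tab$sample_j == "s02"],
               b$deviation["s01", "s02"])
})
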