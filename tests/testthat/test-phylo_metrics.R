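test_that("patristic distances satisfy the worked example and axioms", {
  d <- patristic_distances(micro_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["C", "D"], 2)
  expect_equal(diag(d), setNames(rep(0, 4), c("A", "B", "C", "D")))
  expect_identical(d, t(d))
})

test_that("metrics match brute-force oracles on random instances", {
  for (case in 1:50) {
    n_taxa <- sample(4:20, 1)
    n_samp <- sample(2:8, 1)
    tr <- simulate_tree(n_taxa, 1, rng_seed = 100 + case)
    cm <- random_cm(tr, n_samp, seed = 200 + case)
    d <- patristic_distances(tr)

    expect_lt(max(abs(d - bf_patristic(tr))), 1e-12)
    expect_lt(max(abs(beta_mntd(cm, d) - bf_bmntd(cm, d))), 1e-10)
    expect_lt(max(abs(beta_mpd(cm, d) - bf_bmpd(cm, d))), 1e-10)
    expect_lt(max(abs(faith_pd(cm, tr) - bf_pd(cm, tr))), 1e-10)
    expect_lt(max(abs(bray_curtis(cm) - bf_bray(cm))), 1e-10)
  }
})

test_that("metrics agree with picante and vegan on a random instance", {
  skip_if_not_installed("picante")
  skip_if_not_installed("vegan")
  tr <- simulate_tree(15, 1, rng_seed = 7)
  cm <- random_cm(tr, 5, seed = 8)
  d <- patristic_distances(tr)

  pc_nt <- as.matrix(picante::comdistnt(t(cm), d, abundance.weighted = TRUE))
  mine_nt <- beta_mntd(cm, d)
  expect_lt(max(abs(mine_nt[rownames(pc_nt), colnames(pc_nt)] - pc_nt),
                na.rm = TRUE), 1e-10)

  pc_pd <- picante::pd(t(cm), tr, include.root = TRUE)
  expect_lt(max(abs(faith_pd(cm, tr) - pc_pd$PD)), 1e-10)

  vg <- as.matrix(vegan::vegdist(t(cm), method = "bray"))
  expect_lt(max(abs(bray_curtis(cm)[rownames(vg), colnames(vg)] - vg)),
            1e-10)
})

test_that("worked micro-examples evaluate exactly", {
  tr <- micro_tree()
  d <- patristic_distances(tr)
  cm <- micro_cm()

  expect_equal(beta_mntd(cm, d)["j", "k"], 4)
  expect_equal(beta_mpd(cm, d)["j", "k"], 4)

  cm2 <- matrix(0, 4, 2, dimnames = dimnames(cm))
  cm2[c("A", "C"), "j"] <- c(3, 1)
  cm2[c("B", "D"), "k"] <- c(1, 1)
  expect_equal(beta_mntd(cm2, d)["j", "k"], 2)

  cmj <- cm[, c("j", "j")]
  colnames(cmj) <- c("j1", "j2")
  expect_equal(beta_mpd(cmj, d)["j1", "j2"], 1)
  expect_equal(beta_mntd(cmj, d)["j1", "j2"], 0)  # identical communities

  expect_equal(unname(faith_pd(cm, tr)["j"]), 3)
  allcm <- matrix(1, 4, 1, dimnames = list(c("A", "B", "C", "D"), "all"))
  expect_equal(unname(faith_pd(allcm, tr)), 6)

  single <- matrix(c(1, 0, 0, 0), 4, 2,
                   dimnames = list(c("A", "B", "C", "D"), c("x", "y")))
  single[, 2] <- single[, 1]
  expect_equal(beta_mpd(single, d)["x", "y"], 0)
})

test_that("beta metrics are invariant to joint taxon permutation", {
  tr <- simulate_tree(12, 1, rng_seed = 33)
  cm <- random_cm(tr, 4, seed = 34)
  d <- patristic_distances(tr)
  perm <- sample(rownames(cm))
  expect_equal(beta_mntd(cm[perm, ], d[perm, perm]), beta_mntd(cm, d))
  expect_equal(beta_mpd(cm[perm, ], d[perm, perm]), beta_mpd(cm, d))
})

test_that("ses.PD flags degenerate nulls and detects clustering", {
  tr <- simulate_tree(20, 1, rng_seed = 55)
  # a sample containing every taxon: all shuffles identical
  allcm <- matrix(1, 20, 1, dimnames = list(tr$tip.label, "all"))
  res <- ses_pd(allcm, tr, n_null = 99, rng_seed = 56)
  expect_false(res$defined[1])
  expect_true(is.na(res$ses_pd[1]))

  # single tip on an ultrametric tree: PD = depth regardless of shuffle
  one <- matrix(c(1, rep(0, 19)), 20, 1,
                dimnames = list(tr$tip.label, "one"))
  res1 <- ses_pd(one, tr, n_null = 99, rng_seed = 57)
  expect_false(res1$defined[1])

  # clade-confined communities have ses.PD < 0 on average
  ses_clade <- vapply(1:30, function(s) {
    str <- simulate_structured_tree(10, 5, rng_seed = 900 + s)
    cm <- matrix(0, 50, 2, dimnames = list(str$tip.label, c("clade", "rand")))
    cm[c(paste0("t1_", 1:5), paste0("t2_", 1:5)), "clade"] <- 1
    set.seed(950 + s)
    cm[sample(str$tip.label, 10), "rand"] <- 1
    ses_pd(cm, str, n_null = 199, rng_seed = 990 + s)$ses_pd[1]
  }, numeric(1))
  expect_lt(mean(ses_clade), -1)
})
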