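test_that("niche optima are abundance-weighted means of the axis", {
  cm <- matrix(c(2, 1, 0, 3, 2, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  cm["A", ] <- c(2, 0, 2)
  cm["B", ] <- c(0, 4, 0)
  axis <- c(s1 = 0, s2 = 5.25, s3 = 10.5)
  no <- niche_optima(cm, axis)
  expect_equal(no$optimum[no$taxon == "A"], 5.25)
  expect_equal(no$optimum[no$taxon == "B"], 5.25)  # single-sample taxon

  # bounded by the axis range, linear under rescaling
  tr <- simulate_tree(15, 1, rng_seed = 1)
  cm2 <- random_cm(tr, 6, seed = 2)
  ax <- setNames(seq(0, 28, length.out = 6), colnames(cm2))
  no2 <- niche_optima(cm2, ax)
  expect_true(all(no2$optimum >= 0 & no2$optimum <= 28))
  no3 <- niche_optima(cm2, 2 * ax + 5)
  expect_equal(no3$optimum, 2 * no2$optimum + 5)

  cm2[3, ] <- 0
  expect_message(niche_optima(cm2, ax), "zero total")
})

test_that("Pagel's lambda ML fit is internally consistent", {
  tr <- simulate_tree(60, 1, rng_seed = 11)
  x <- evolve_trait(tr, 1, 0.7, rng_seed = 12)
  fit <- pagels_lambda(tr, x)
  expect_true(fit$identifiable)
  expect_gte(fit$lambda, 0)
  expect_lte(fit$lambda, 1)
  expect_gte(fit$logL, fit$logL0 - 1e-8)
  f0 <- assemblage:::lambda_profile_loglik(0, ape::vcv(tr), x[tr$tip.label])
  f1 <- assemblage:::lambda_profile_loglik(1, ape::vcv(tr), x[tr$tip.label])
  expect_gte(fit$logL, max(as.numeric(f0), as.numeric(f1)) - 1e-8)
  expect_gte(fit$p, 0)
  expect_lte(fit$p, 1)
})

test_that("Pagel's lambda matches an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(50, 1, rng_seed = 21)
  x <- evolve_trait(tr, 1, 0.5, rng_seed = 22)
  mine <- pagels_lambda(tr, x)
  ph <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(mine$lambda, ph$lambda, tolerance = 1e-4)
  expect_equal(mine$logL, ph$logL, tolerance = 1e-6)
})

test_that("a star-like tree leaves lambda unidentifiable", {
  # zero-length internal branches: no shared path length between any tips
  star <- ape::read.tree(text = "(((A:1,B:1):0,C:1):0,D:1);")
  x <- setNames(rnorm(4), star$tip.label)
  w <- capture_warnings(fit <- pagels_lambda(star, x))
  expect_true(any(grepl("unidentifiable", w)))
  expect_false(fit$identifiable)
  expect_true(is.na(fit$lambda))
})

test_that("the correlogram partitions distances into 0.02 classes", {
  tr <- simulate_structured_tree(20, 5, rng_seed = 31)
  trt <- evolve_trait(tr, 1, 1, rng_seed = 32)
  pd <- patristic_distances(tr)
  nd <- abs(outer(trt, trt, "-"))
  dimnames(nd) <- dimnames(pd)
  mc <- mantel_correlogram(nd, pd, n_perm = 99, rng_seed = 33)
  expect_equal(nrow(mc), 50)                  # 1 / 0.02 classes
  expect_equal(mc$lower, seq(0, 0.98, 0.02))
  expect_equal(sum(mc$n_pairs), choose(100, 2))
  expect_false(any(mc$tested & mc$n_pairs < 10))
})

test_that("correlogram r equals the vegan membership Mantel statistic", {
  skip_if_not_installed("vegan")
  tr <- simulate_tree(40, 1, rng_seed = 41)
  trt <- evolve_trait(tr, 1, 1, rng_seed = 42)
  pd <- patristic_distances(tr)
  nd <- abs(outer(trt, trt, "-"))
  dimnames(nd) <- dimnames(pd)
  mc <- mantel_correlogram(nd, pd, n_perm = 99, rng_seed = 43)
  vm <- vegan::mantel.correlog(stats::as.dist(nd),
                               D.geo = stats::as.dist(pd / max(pd)),
                               break.pts = seq(0, 1, 0.02),
                               cutoff = FALSE, nperm = 0)
  vr <- vm$mantel.res[, "Mantel.cor"]
  ok <- mc$n_pairs > 0 & !is.na(vr)
  expect_lt(max(abs(mc$r[ok] - vr[ok]), na.rm = TRUE), 1e-12)
})

test_that("Brownian traits show short-distance phylogenetic signal", {
  tr <- simulate_structured_tree(20, 5, rng_seed = 51)
  trt <- evolve_trait(tr, 1, 1, rng_seed = 52)
  pd <- patristic_distances(tr)
  nd <- abs(outer(trt, trt, "-"))
  dimnames(nd) <- dimnames(pd)
  mc <- mantel_correlogram(nd, pd, n_perm = 499, rng_seed = 53)
  tested <- mc[mc$tested & !is.na(mc$r), ]
  expect_gt(tested$r[1], 0)
  expect_true(tested$significant[1])
  # signal concentrated at short distances: the shortest quartile of
  # classes is positive on average and exceeds the deepest quartile
  q <- max(1, nrow(tested) %/% 4)
  expect_gt(mean(head(tested$r, q)), 0)
  expect_gt(mean(head(tested$r, q)), mean(tail(tested$r, q)))
})

test_that("degenerate niche distances are rejected", {
  tr <- simulate_tree(10, 1, rng_seed = 61)
  pd <- patristic_distances(tr)
  nd <- matrix(1, 10, 10, dimnames = dimnames(pd)); diag(nd) <- 0
  expect_error(mantel_correlogram(nd * 0, pd), "degenerate")
})
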