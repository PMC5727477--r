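test_that("simulate_tree is a reproducible pure-birth process", {
  expect_error(simulate_tree(1), "n_tips")
  t2 <- simulate_tree(2, rng_seed = 1)
  depths <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(depths[1], depths[2])  # ultrametric cherry

  a <- ape::write.tree(simulate_tree(8, 1, rng_seed = 5))
  b <- ape::write.tree(simulate_tree(8, 1, rng_seed = 5))
  expect_identical(a, b)
})

test_that("pure-birth internode intervals have exponential moments", {
  # while k lineages exist the wait to the next split is Exp(k * birth);
  # k * dt should therefore have mean 1 and sd 1
  ints <- unlist(lapply(1:200, function(s) {
    tr <- simulate_tree(20, 1, rng_seed = 7000 + s)
    bt <- sort(unname(ape::branching.times(tr)), decreasing = TRUE)
    dt <- bt[-length(bt)] - bt[-1]     # i-th interval has i+1 lineages
    (2:length(bt)) * dt
  }))
  expect_gt(mean(ints), 0.85)
  expect_lt(mean(ints), 1.1)
  expect_gt(sd(ints), 0.8)
  expect_lt(sd(ints), 1.2)
})

test_that("structured trees have tight clusters on a deep backbone", {
  tr <- simulate_structured_tree(20, 5, depth_ratio = 10, rng_seed = 3)
  expect_equal(ape::Ntip(tr), 100)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  d <- patristic_distances(tr)
  within <- d[paste0("t1_", 1:5), paste0("t1_", 1:5)]
  across <- d[paste0("t1_", 1:5), paste0("t2_", 1:5)]
  expect_lt(max(within), min(across))
})

test_that("evolve_trait draws from the lambda-scaled Brownian covariance", {
  tr <- micro_tree()
  # lambda = 1 cherry: cov(tips) = sigma2 * shared stem length
  V1 <- assemblage:::lambda_cov(tr, sigma2 = 2, lambda = 1)
  expect_equal(V1["A", "B"], 2 * 1)
  expect_equal(V1["A", "A"], 2 * 2)
  expect_equal(V1["A", "C"], 0)
  # lambda = 0: off-diagonals zeroed, diagonal (tip depth) unchanged
  V0 <- assemblage:::lambda_cov(tr, sigma2 = 2, lambda = 0)
  expect_true(all(V0[upper.tri(V0)] == 0))
  expect_equal(diag(V0), diag(V1))

  expect_error(evolve_trait(tr, 1, 1.5), "lambda")

  # Monte-Carlo: empirical tip covariance ~ analytic shared-path matrix
  tr2 <- simulate_tree(40, 1, rng_seed = 11)
  V <- assemblage:::lambda_cov(tr2, 1, 1)
  draws <- sapply(1:500, function(i) evolve_trait(tr2, 1, 1,
                                                  rng_seed = 8000 + i))
  emp <- cov(t(draws))
  expect_gt(cor(emp[upper.tri(emp)], V[upper.tri(V)]), 0.95)
  expect_lt(mean(abs(emp - V)), 0.2 * mean(diag(V)))
})

test_that("assemble_communities respects the sampling weight model", {
  tr <- simulate_tree(30, 1, rng_seed = 21)
  trt <- evolve_trait(tr, 1, 1, rng_seed = 22)

  # neutral limit: relative abundances track base abundances
  cfg <- sim_config(n_tips = 30, scenario = "neutral", n_samples = 1,
                    n_individuals = 1e6, drift_sd = 0, rng_seed = 23)
  out <- assemble_communities(tr, trt, cfg)
  rel <- out$community[, 1] / sum(out$community[, 1])
  base_rel <- out$truth$base_abundance / sum(out$truth$base_abundance)
  expect_lt(max(abs(rel - base_rel)), 0.005)

  # degenerate filter: environment exactly on one taxon's niche
  cfg2 <- sim_config(n_tips = 30, scenario = "homogeneous_selection",
                     n_samples = 1, n_individuals = 1e4,
                     env_values = trt[["t5"]], filter_width = 1e-6,
                     filter_floor = 0, drift_sd = 0,
                     colonization_prob = 1, rng_seed = 24)
  out2 <- assemble_communities(tr, trt, cfg2)
  expect_gt(out2$community["t5", 1] / sum(out2$community[, 1]), 0.999)

  # reproducibility from (config, seed)
  cfg3 <- sim_config(n_tips = 30, scenario = "dispersal_limited",
                     rng_seed = 25)
  expect_identical(assemble_communities(tr, trt, cfg3)$community,
                   assemble_communities(tr, trt, cfg3)$community)
})

test_that("variable selection separates environment blocks", {
  cfg <- sim_config(n_tips = 100, scenario = "variable_selection",
                    rng_seed = 31)
  sim <- simulate_assembly(cfg)
  bc <- bray_curtis(sim$community)
  g <- sim$metadata$group
  between <- outer(g, g, "!=")[upper.tri(bc)]
  v <- bc[upper.tri(bc)]
  expect_gt(mean(v[between]), mean(v[!between]))
})

test_that("pulse series place taxa at their temporal optima", {
  expect_error(
    simulate_pulse_series(micro_tree(),
                          setNames(rep(0, 4), c("A", "B", "C", "D")),
                          sim_config(n_tips = 4, rng_seed = 1),
                          times_h = c(0, 2)),
    "strictly positive")

  tr <- simulate_tree(32, 1, rng_seed = 41)
  trt <- evolve_trait(tr, 1, 1, rng_seed = 42)
  opt <- rescale_traits(trt, log(0.5), log(144))
  cfg <- sim_config(n_tips = 32, scenario = "neutral", drift_sd = 0,
                    n_individuals = 1e5, rng_seed = 43)
  ps <- simulate_pulse_series(tr, opt, cfg)
  # a taxon with optimum at the first time point peaks there
  first <- names(which.min(abs(opt - log(0.5))))
  rel <- sweep(ps$community, 2, colSums(ps$community), "/")
  expect_equal(which.max(rel[first, ]), 1L, ignore_attr = TRUE)
})

test_that("abundance-weighted optima recover the temporal niche", {
  tr <- simulate_tree(64, 1, rng_seed = 51)
  trt <- evolve_trait(tr, 1, 1, rng_seed = 52)
  opt <- rescale_traits(trt, log(0.5), log(144))
  cfg <- sim_config(n_tips = 64, scenario = "neutral",
                    n_individuals = 1e5, rng_seed = 53)
  ps <- simulate_pulse_series(tr, opt, cfg)
  no <- niche_optima(ps$community,
                     setNames(ps$metadata$ln_time, ps$metadata$sample_id))
  r <- cor(no$optimum, ps$truth$optima[no$taxon])
  expect_gt(r, 0.8)
})
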