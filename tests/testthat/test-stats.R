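test_that("Mantel test handles identity and anti-correlation", {
  set.seed(1)
  x <- matrix(rnorm(24), 12)
  d1 <- as.matrix(dist(x))
  ids <- sprintf("s%02d", 1:12)
  dimnames(d1) <- list(ids, ids)
  r <- mantel_test(d1, d1, n_perm = 199, rng_seed = 2)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 200)

  d2 <- max(d1) - d1; diag(d2) <- 0
  r2 <- mantel_test(d1, d2, n_perm = 199, tail = "greater", rng_seed = 3)
  expect_equal(r2$r, -1)
  expect_gt(r2$p, 0.95)

  expect_error(mantel_test(d1 * 0, d1, n_perm = 99), "constant")
})

test_that("Mantel r agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(4)
  a <- matrix(rnorm(30), 10); b <- a + matrix(rnorm(30, sd = 2), 10)
  d1 <- as.matrix(dist(a)); d2 <- as.matrix(dist(b))
  ids <- letters[1:10]
  dimnames(d1) <- dimnames(d2) <- list(ids, ids)
  mine <- mantel_test(d1, d2, n_perm = 199, rng_seed = 5)
  vg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 199)
  expect_equal(mine$r, unname(vg$statistic), tolerance = 1e-12)
})

test_that("mean deviation test behaves at its extremes", {
  z <- mean_deviation_test(rep(0, 10), n_perm = 199, rng_seed = 6)
  expect_equal(z$mean, 0)
  expect_equal(z$p, 1)

  big <- mean_deviation_test(rep(5, 20), n_perm = 999, rng_seed = 7)
  expect_lt(big$p, 0.01)

  expect_error(mean_deviation_test(3), "at least 2")

  withna <- mean_deviation_test(c(1, -1, 2, NA), n_perm = 199, rng_seed = 8)
  expect_equal(withna$n, 3L)
})

test_that("PERMDISP matches direct geometry and detects dispersion shifts", {
  set.seed(9)
  A <- matrix(rnorm(40), 20)
  cent <- colMeans(A)
  direct <- sqrt(rowSums((A - matrix(cent, 20, 2, byrow = TRUE))^2))
  dA <- as.matrix(dist(A))
  dimnames(dA) <- list(paste0("a", 1:20), paste0("a", 1:20))
  d2c <- assemblage:::dispersion_to_centroid(dA)
  expect_lt(max(abs(d2c - direct)), 1e-10)

  B <- matrix(rnorm(40), 20) * 3
  d <- as.matrix(dist(rbind(A, B)))
  dimnames(d) <- list(paste0("s", 1:40), paste0("s", 1:40))
  res <- permdisp(d, rep(c("A", "B"), each = 20), n_perm = 999,
                  rng_seed = 10)
  expect_lt(res$p, 0.05)
  expect_gt(res$group_means[["B"]], res$group_means[["A"]])

  # translated copies have equal dispersion
  C <- A + 10
  dT <- as.matrix(dist(rbind(A, C)))
  dimnames(dT) <- list(paste0("s", 1:40), paste0("s", 1:40))
  resT <- permdisp(dT, rep(c("A", "C"), each = 20), n_perm = 499,
                   rng_seed = 11)
  expect_equal(resT$group_means[["A"]], resT$group_means[["C"]],
               tolerance = 1e-10)

  expect_error(permdisp(dA, rep("A", 20)), "2 groups")
})

test_that("signed deviation matrices are shifted before embedding", {
  m <- matrix(c(0, -1, 2, -1, 0, 1, 2, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_message(assemblage:::shift_nonnegative(m), "shifting")
})

test_that("segmented fits recover slopes and handle degenerate input", {
  # exact two-line data
  x <- c(0, 1.75, 5.25, 10.5, 17.5, 28)
  y <- ifelse(x <= 10.5, 2 * x, 21 - 1 * (x - 10.5))
  fit <- suppressWarnings(   # exact fit: summary.lm warns
    segmented_fit(x, y, breakpoint = 10.5, n_boot = 99, rng_seed = 12))
  expect_equal(fit$low$r_squared, 1)
  expect_equal(fit$high$r_squared, 1)
  expect_equal(fit$low$slope, 2, tolerance = 1e-10)
  expect_equal(fit$high$slope, -1, tolerance = 1e-10)
  expect_equal(fit$low$n, 4L)       # boundary point in both segments
  expect_equal(fit$high$n, 3L)

  # constant response
  fitc <- suppressWarnings(
    segmented_fit(x, rep(3, 6), breakpoint = 10.5, n_boot = 99,
                  rng_seed = 13))
  expect_equal(fitc$low$slope, 0, tolerance = 1e-12)
  expect_equal(fitc$low$r_squared, 0)

  # noisy single line: slope within bootstrap CI in both segments
  set.seed(14)
  xs <- seq(0, 10, length.out = 40)
  ys <- 2 * xs + rnorm(40, sd = 0.1)
  fs <- segmented_fit(xs, ys, breakpoint = 5, n_boot = 499, rng_seed = 15)
  expect_true(fs$low$slope_ci[1] < 2 && 2 < fs$low$slope_ci[2])
  expect_true(fs$high$slope_ci[1] < 2 && 2 < fs$high$slope_ci[2])

  expect_error(segmented_fit(1:4, 1:4, breakpoint = 1.5), "3 points")
})

test_that("ln_abs_diff transforms with zero-difference handling", {
  ax <- c(a = 1, b = 1, c = 3)
  expect_message(m <- ln_abs_diff(ax), "zero difference")
  expect_equal(m["a", "c"], log(2))
  expect_equal(m["a", "b"], log(1))      # half the smallest positive diff (2/2)
  expect_error(ln_abs_diff(c(1, 1, 1)), "all pairwise")
})
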