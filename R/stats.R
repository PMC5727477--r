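#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangles, with
#' significance from jointly permuting rows/columns of the first matrix.
#' The default tail is `"greater"` (one-tailed for positive association,
#' the convention under which a negative observed r yields p near 1).
#' `NA` entries (e.g. undefined deviations) are dropped pairwise, in the
#' observed and every permuted correlation alike.
#'
#' @param d1,d2 Symmetric matrices over the same IDs in the same order.
#' @param n_perm Number of permutations (default 10000).
#' @param tail `"greater"`, `"less"`, or `"two-sided"`.
#' @param rng_seed Optional integer seed.
#' @return Object of class `"mantel_result"`: `r`, `p`, `n_perm`, `tail`,
#'   `n_pairs`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000,
                        tail = c("greater", "less", "two-sided"),
                        rng_seed = NULL) {
  tail <- match.arg(tail)
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.matrix(d1) || !is.matrix(d2) || !all(dim(d1) == dim(d2)))
    stop("d1 and d2 must be square matrices of equal size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("d1 and d2 must share IDs in the same order")
  ut <- which(upper.tri(d1))
  v2 <- d2[ut]
  v1 <- d1[ut]
  ok <- !is.na(v1) & !is.na(v2)
  if (sd(v1[ok]) < 1e-12 || sd(v2[ok]) < 1e-12)
    stop("constant matrix: Mantel r undefined")
  r_obs <- cor(v1[ok], v2[ok])
  n <- nrow(d1)
  count_hi <- 0L; count_lo <- 0L
  with_seed(rng_seed, {
    for (b in seq_len(n_perm)) {
      pidx <- sample.int(n)
      vp <- d1[pidx, pidx][ut]
      okp <- !is.na(vp) & !is.na(v2)
      rp <- suppressWarnings(cor(vp[okp], v2[okp]))
      if (is.na(rp)) next
      if (rp >= r_obs - 1e-12) count_hi <- count_hi + 1L
      if (rp <= r_obs + 1e-12) count_lo <- count_lo + 1L
    }
  })
  p <- switch(tail,
              greater = (count_hi + 1) / (n_perm + 1),
              less = (count_lo + 1) / (n_perm + 1),
              `two-sided` = min(1, 2 * (min(count_hi, count_lo) + 1) /
                                  (n_perm + 1)))
  structure(list(r = r_obs, p = p, n_perm = n_perm, tail = tail,
                 n_pairs = sum(ok), seed = rng_seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%s tail, %d permutations, %d pairs)\n",
              x$r, x$p, x$tail, x$n_perm, x$n_pairs))
  invisible(x)
}

#' Monte Carlo test of a mean deviation against zero
#'
#' Tests whether the mean of a set of deviations (e.g. betaNTI values
#' within a group) differs from the null expectation of zero, using
#' independent random sign flips of the values (valid when the null
#' distribution of each deviation is symmetric about zero). Two-tailed.
#'
#' @param values Numeric vector of deviations (NA dropped).
#' @param n_perm Number of Monte Carlo sign-flip draws (default 10000).
#' @param rng_seed Optional integer seed.
#' @param group Optional group label carried into the result.
#' @return Object of class `"group_deviation"`: `group`, `mean`, `sd`,
#'   `n`, `p`, `n_perm`.
#' @export
mean_deviation_test <- function(values, n_perm = 10000, rng_seed = NULL,
                                group = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  mu <- mean(values)
  sdev <- sd(values)
  if (all(values == 0)) {
    p <- 1
  } else {
    with_seed(rng_seed, {
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n)
      null_means <- colMeans(values * signs)
      p <- min(1, (sum(abs(null_means) >= abs(mu) - 1e-12) + 1) /
                 (n_perm + 1))
    })
  }
  structure(list(group = group, mean = mu, sd = sdev, n = n, p = p,
                 n_perm = n_perm, seed = rng_seed),
            class = "group_deviation")
}

#' @export
print.group_deviation <- function(x, ...) {
  cat(sprintf("Mean deviation%s: mu = %.3f, sd = %.3f (n = %d), Monte Carlo p = %.4g\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$mean, x$sd, x$n, x$p))
  invisible(x)
}

# Shift a signed symmetric deviation matrix into a non-negative
# dissimilarity for embedding (off-diagonal entries shifted by |min|).
shift_nonnegative <- function(m) {
  off <- m[upper.tri(m)]
  mn <- min(off, na.rm = TRUE)
  if (mn < 0) {
    message(sprintf("shifting off-diagonal values by %.3f to remove negatives before embedding",
                    -mn))
    m <- m - mn
    diag(m) <- 0
  }
  m
}

#' Multivariate homogeneity of group dispersions (PERMDISP)
#'
#' Embeds the dissimilarity matrix by principal-coordinates analysis
#' (negative eigenvalues handled by the imaginary-part correction),
#' computes each sample's distance to its group centroid, and tests the
#' equality of group dispersions by permuting group labels. Backed by
#' [vegan::betadisper()] with `type = "centroid"`. Signed deviation
#' matrices (e.g. betaNTI) are first shifted by the absolute minimum of
#' the off-diagonal values so all dissimilarities are non-negative.
#'
#' @param dmat Symmetric dissimilarity (or signed deviation) matrix.
#' @param groups Group labels, one per row of `dmat` (>= 2 groups, each
#'   with >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param rng_seed Optional integer seed.
#' @return Object of class `"permdisp_result"`: `distances` (per-sample
#'   distance to own centroid), `group_means`, `F`, `p`, `n_perm`.
#' @export
permdisp <- function(dmat, groups, n_perm = 999, rng_seed = NULL) {
  if (!is.matrix(dmat) || nrow(dmat) != ncol(dmat))
    stop("dmat must be a square matrix")
  groups <- as.factor(groups)
  if (length(groups) != nrow(dmat))
    stop("groups length must match dmat")
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  m <- shift_nonnegative(dmat)
  bd <- vegan::betadisper(stats::as.dist(m), groups, type = "centroid")
  pt <- with_seed(rng_seed,
                  vegan::permutest(bd, permutations = n_perm))
  tab <- pt$tab
  structure(list(distances = bd$distances,
                 group_means = tapply(bd$distances, groups, mean),
                 F = tab$F[1L], p = tab$`Pr(>F)`[1L],
                 n_perm = n_perm, seed = rng_seed),
            class = "permdisp_result")
}

#' @export
print.permdisp_result <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.3f, p = %.4g (%d permutations)\n",
              x$F, x$p, x$n_perm))
  cat("  group mean distance-to-centroid:\n")
  for (g in names(x$group_means))
    cat(sprintf("    %-12s %.4f\n", g, x$group_means[[g]]))
  invisible(x)
}

# Distance-to-centroid of a single point cloud given its dissimilarity
# matrix (single-group PCoA embedding; used by the pulse pipeline when
# pools have no between-pool dissimilarities).
dispersion_to_centroid <- function(dmat) {
  m <- shift_nonnegative(dmat)
  g <- factor(rep("all", nrow(m)))
  # betadisper needs >= 1 group; with one group distances are what we want
  bd <- vegan::betadisper(stats::as.dist(m), g, type = "centroid")
  setNames(bd$distances, rownames(m))
}

# Two-sample permutation test on a difference in means (used for the
# between-pool dispersion comparison).
two_sample_perm_test <- function(x, y, n_perm = 10000, rng_seed = NULL) {
  obs <- mean(x) - mean(y)
  z <- c(x, y); nx <- length(x)
  with_seed(rng_seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(z), nx)
      if (abs(mean(z[idx]) - mean(z[-idx])) >= abs(obs) - 1e-12)
        count <- count + 1L
    }
    list(diff = obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm)
  })
}

#' Segmented linear regression with a fixed breakpoint
#'
#' Fits independent ordinary least-squares lines on the two sides of a
#' user-fixed breakpoint; the boundary point is included in both segments
#' (matching range conventions such as 0-10.5 and 10.5-28). Per-segment
#' slope, intercept, R-squared and slope-test p are reported with
#' case-resampling percentile bootstrap 95% intervals and prediction
#' bands.
#'
#' @param x,y Numeric vectors.
#' @param breakpoint Axis value splitting the segments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param rng_seed Optional integer seed.
#' @return Object of class `"segmented_fit"`: per-segment `slope`,
#'   `intercept`, `r_squared`, `p`, `n`, `slope_ci`, and a `bands`
#'   data.frame (segment, x, fit, lower, upper).
#' @export
segmented_fit <- function(x, y, breakpoint, n_boot = 1000,
                          rng_seed = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  segs <- list(low = x <= breakpoint, high = x >= breakpoint)
  if (any(vapply(segs, sum, integer(1)) < 3))
    stop("each segment needs at least 3 points")
  fit_one <- function(xx, yy) {
    fm <- lm(yy ~ xx)
    sm <- summary(fm)
    r2 <- sm$r.squared
    pv <- if (nrow(sm$coefficients) < 2L || sd(yy) < 1e-12) 1
          else sm$coefficients[2L, 4L]
    if (!is.finite(r2)) r2 <- 0   # constant response
    list(slope = unname(coef(fm)["xx"]), intercept = coef(fm)[[1L]],
         r_squared = r2, p = pv, n = length(xx), model = fm)
  }
  out <- list(breakpoint = breakpoint, n_boot = n_boot, seed = rng_seed)
  bands <- NULL
  with_seed(rng_seed, {
    for (s in names(segs)) {
      xx <- x[segs[[s]]]; yy <- y[segs[[s]]]
      f <- fit_one(xx, yy)
      grid <- seq(min(xx), max(xx), length.out = 50L)
      boot_slope <- numeric(n_boot)
      boot_pred <- matrix(NA_real_, n_boot, length(grid))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(length(xx), replace = TRUE)
        if (length(unique(xx[idx])) < 2) { boot_slope[b] <- NA; next }
        cf <- coef(lm(yy[idx] ~ xx[idx]))
        boot_slope[b] <- cf[[2L]]
        boot_pred[b, ] <- cf[[1L]] + cf[[2L]] * grid
      }
      f$slope_ci <- quantile(boot_slope, c(0.025, 0.975), na.rm = TRUE,
                             names = FALSE)
      lo <- apply(boot_pred, 2L, quantile, 0.025, na.rm = TRUE)
      hi <- apply(boot_pred, 2L, quantile, 0.975, na.rm = TRUE)
      bands <- rbind(bands, data.frame(
        segment = s, x = grid,
        fit = f$intercept + f$slope * grid, lower = lo, upper = hi))
      f$model <- NULL
      out[[s]] <- f
    }
  })
  out$bands <- bands
  class(out) <- "segmented_fit"
  out
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf("Segmented fit, breakpoint at %g (boundary in both segments)\n",
              x$breakpoint))
  for (s in c("low", "high")) {
    f <- x[[s]]
    cat(sprintf("  %s: slope %.3f [%.3f, %.3f], R2 = %.3f, p = %.3g (n = %d)\n",
                s, f$slope, f$slope_ci[1L], f$slope_ci[2L], f$r_squared,
                f$p, f$n))
  }
  invisible(x)
}

#' Ln-transform pairwise absolute differences of an axis
#'
#' Builds the matrix `ln |a_i - a_j|` used as the predictor in turnover
#' regressions and Mantel tests. Zero differences (within-level pairs)
#' are replaced by ln(half the smallest positive difference), with a
#' message, since the log of zero is undefined.
#'
#' @param axis Numeric per-sample values (named or positional).
#' @return Symmetric matrix of log absolute differences (diagonal 0).
#' @export
ln_abs_diff <- function(axis) {
  d <- abs(outer(axis, axis, "-"))
  off <- d[upper.tri(d)]
  pos <- off[off > 0]
  if (length(pos) == 0) stop("all pairwise differences are zero")
  if (any(off == 0)) {
    repl <- min(pos) / 2
    message(sprintf("ln_abs_diff: %d zero difference(s) replaced by %.4g before log",
                    sum(off == 0), repl))
    d[d == 0] <- repl
  }
  out <- log(d)
  diag(out) <- 0
  if (!is.null(names(axis))) dimnames(out) <- list(names(axis), names(axis))
  out
}
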