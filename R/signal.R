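#' Abundance-weighted niche optima
#'
#' Each taxon's niche optimum along an environmental or temporal axis is
#' the abundance-weighted mean of the axis values of the samples it occurs
#' in: `optimum_i = sum_s x_is axis_s / sum_s x_is`. Taxa with zero total
#' abundance are excluded with a message.
#'
#' @param cm Community matrix (taxa x samples).
#' @param axis Numeric per-sample axis values, either named by sample ID or
#'   in the column order of `cm` (units: e.g. g N m-2 yr-1, or ln-hours).
#' @return data.frame with columns `taxon`, `optimum`, `total_abundance`.
#' @export
#' @examples
#' cm <- matrix(c(2, 1, 0, 3, 2, 0), nrow = 2,
#'              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' niche_optima(cm, c(s1 = 0, s2 = 5.25, s3 = 10.5))
niche_optima <- function(cm, axis) {
  cm <- check_community(cm)
  if (!is.null(names(axis))) {
    if (!all(colnames(cm) %in% names(axis)))
      stop("axis values missing for some samples")
    axis <- axis[colnames(cm)]
  } else if (length(axis) != ncol(cm)) {
    stop("axis length must match the number of samples")
  }
  if (anyNA(axis) || any(!is.finite(axis)))
    stop("axis values must be finite")
  tot <- rowSums(cm)
  if (any(tot == 0))
    message(sprintf("niche_optima: %d taxon/taxa with zero total abundance excluded",
                    sum(tot == 0)))
  keep <- tot > 0
  opt <- as.numeric(cm[keep, , drop = FALSE] %*% axis) / tot[keep]
  data.frame(taxon = rownames(cm)[keep], optimum = opt,
             total_abundance = tot[keep], stringsAsFactors = FALSE)
}

# Profile log-likelihood of the lambda model: MVN with covariance
# sigma2 * C(lambda), root state and sigma2 profiled analytically by GLS.
lambda_profile_loglik <- function(lambda, C, x) {
  n <- length(x)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  R <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet <- 2 * sum(log(diag(R)))
  ones <- rep(1, n)
  iC1 <- backsolve(R, forwardsolve(t(R), ones))
  iCx <- backsolve(R, forwardsolve(t(R), x))
  root <- sum(iCx) / sum(iC1)
  e <- x - root
  iCe <- backsolve(R, forwardsolve(t(R), e))
  s2 <- sum(e * iCe) / n
  if (s2 <= 0) return(-Inf)
  ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  attr(ll, "sigma2") <- s2
  attr(ll, "root") <- root
  ll
}

#' Pagel's lambda phylogenetic signal (maximum likelihood)
#'
#' Fits by maximum likelihood the multivariate-normal trait model whose
#' covariance is the Brownian shared-path-length matrix with off-diagonal
#' entries scaled by lambda (diagonal unchanged); sigma-squared and the
#' root state are profiled analytically and lambda is optimized on
#' \[0, 1\] to tolerance 1e-8. Significance is a likelihood-ratio test of
#' lambda = 0 (no signal): because lambda = 0 is on the boundary of the
#' parameter space, the LR statistic is referred to an equal mixture of a
#' point mass at zero and chi-squared(1), i.e. the chi-squared(1) tail
#' probability is halved.
#'
#' @param tree A validated `"phylo"` tree (>= 3 tips).
#' @param trait Named numeric vector of tip trait values.
#' @return Object of class `"pagels_lambda"`: `lambda`, `sigma2`, `root`,
#'   `logL`, `logL0`, `LR`, `p`, `n`, `identifiable`.
#' @export
pagels_lambda <- function(tree, trait) {
  validate_tree(tree)
  if (is.null(names(trait)) || !setequal(names(trait), tree$tip.label))
    stop("trait must be named by the tree's tip labels")
  trait <- trait[tree$tip.label]
  if (anyNA(trait)) stop("missing trait values")
  n <- length(trait)
  if (n < 3) stop("need at least 3 tips")
  C <- ape::vcv(tree)
  identifiable <- max(abs(C[upper.tri(C)])) > 1e-12 * max(diag(C))
  if (!identifiable) {
    warning("star tree: lambda is unidentifiable")
    return(structure(list(lambda = NA_real_, sigma2 = NA_real_,
                          root = NA_real_, logL = NA_real_,
                          logL0 = NA_real_, LR = NA_real_, p = NA_real_,
                          n = n, identifiable = FALSE),
                     class = "pagels_lambda"))
  }
  f <- function(l) as.numeric(lambda_profile_loglik(l, C, trait))
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  ll <- vapply(cand, f, numeric(1))
  best <- which.max(ll)
  lambda_hat <- cand[best]
  llbest <- lambda_profile_loglik(lambda_hat, C, trait)
  ll0 <- f(0)
  LR <- max(0, 2 * (as.numeric(llbest) - ll0))
  p <- if (LR <= 0) 1 else 0.5 * pchisq(LR, df = 1, lower.tail = FALSE)
  structure(list(lambda = lambda_hat,
                 sigma2 = attr(llbest, "sigma2"),
                 root = attr(llbest, "root"),
                 logL = as.numeric(llbest), logL0 = ll0, LR = LR, p = p,
                 n = n, identifiable = TRUE),
            class = "pagels_lambda")
}

#' @export
print.pagels_lambda <- function(x, ...) {
  if (!x$identifiable) {
    cat("Pagel's lambda: unidentifiable (star tree)\n")
    return(invisible(x))
  }
  cat(sprintf("Pagel's lambda = %.3f (sigma2 = %.4g, n = %d)\n",
              x$lambda, x$sigma2, x$n))
  cat(sprintf("  logL = %.3f, logL(lambda=0) = %.3f, LR = %.3f, p = %.3g\n",
              x$logL, x$logL0, x$LR, x$p))
  invisible(x)
}

#' Mantel correlogram of niche distance against phylogenetic distance
#'
#' Patristic distances are standardized by their maximum (to \[0, 1\]) and
#' partitioned into contiguous classes of width `class_width` from the
#' tips toward the root (half-open intervals, last class closed). For each
#' class the Mantel correlation between the niche distance matrix and the
#' binary within-class membership matrix is computed and sign-flipped so
#' that positive r means taxa in that distance class have more similar
#' niches than average (the autocorrelogram reading). P-values come from
#' permuting taxon labels (two-tailed, `(count + 1)/(n_perm + 1)`) and are
#' corrected progressively (Holm across the classes up to and including
#' each class, in increasing distance order). Classes with fewer than
#' `min_pairs` pairs are reported but not tested.
#'
#' @param niche_dist Distance matrix of niche values (e.g. Euclidean
#'   distances of [niche_optima()] output).
#' @param phylo_dist Patristic distance matrix over the same taxa.
#' @param class_width Width of the standardized distance classes
#'   (default 0.02).
#' @param n_perm Number of permutations (default 1000).
#' @param min_pairs Minimum pairs per class for testing (default 10).
#' @param rng_seed Optional integer seed.
#' @return Object of class `"mantel_correlogram"`: a data.frame with
#'   `class_index`, `lower`, `upper`, `n_pairs`, `r`, `p`, `p_corrected`,
#'   `significant`, `tested`; attribute `n_perm`.
#' @export
mantel_correlogram <- function(niche_dist, phylo_dist, class_width = 0.02,
                               n_perm = 1000, min_pairs = 10,
                               rng_seed = NULL) {
  check_dmat(niche_dist); check_dmat(phylo_dist)
  if (!setequal(rownames(niche_dist), rownames(phylo_dist)))
    stop("matrices cover different taxa")
  if (n_perm < 99) stop("n_perm must be >= 99")
  phylo_dist <- phylo_dist[rownames(niche_dist), rownames(niche_dist)]
  dmax <- max(phylo_dist)
  if (dmax <= 0) stop("degenerate phylogenetic distances (all zero)")
  std <- phylo_dist / dmax
  n <- nrow(std)
  dvec <- upper_vec(niche_dist)
  if (sd(dvec) < 1e-12)
    stop("degenerate niche distances (all equal); r undefined")
  svec <- upper_vec(std)
  n_class <- ceiling(1 / class_width)
  lower <- (seq_len(n_class) - 1) * class_width
  upper <- pmin(lower + class_width, 1)
  cls <- pmin(floor(svec / class_width) + 1L, n_class)  # last class closed
  member <- matrix(0, length(svec), n_class)
  member[cbind(seq_along(svec), cls)] <- 1
  n_pairs <- colSums(member)
  tested <- n_pairs >= min_pairs
  # sign-flipped membership correlation; constant membership -> NA
  safe_cor <- function(v, m) {
    ok <- colSums(m) > 0 & colSums(m) < nrow(m)
    out <- rep(NA_real_, ncol(m))
    if (any(ok)) out[ok] <- -suppressWarnings(cor(v, m[, ok, drop = FALSE]))
    out
  }
  r_obs <- safe_cor(dvec, member)
  pr <- matrix(NA_real_, n_perm, n_class)
  ut <- which(upper.tri(niche_dist))
  with_seed(rng_seed, {
    for (b in seq_len(n_perm)) {
      pidx <- sample.int(n)
      dp <- niche_dist[pidx, pidx][ut]
      pr[b, ] <- safe_cor(dp, member)
    }
  })
  p <- vapply(seq_len(n_class), function(k) {
    if (!tested[k] || is.na(r_obs[k])) return(NA_real_)
    (sum(abs(pr[, k]) >= abs(r_obs[k]) - 1e-12) + 1) / (n_perm + 1)
  }, numeric(1))
  # progressive Holm: class k corrected within the first k tested classes
  p_corr <- rep(NA_real_, n_class)
  tk <- which(tested & !is.na(p))
  for (j in seq_along(tk))
    p_corr[tk[j]] <- stats::p.adjust(p[tk[seq_len(j)]], "holm")[j]
  out <- data.frame(class_index = seq_len(n_class), lower = lower,
                    upper = upper, n_pairs = as.integer(n_pairs),
                    r = r_obs, p = p, p_corrected = p_corr,
                    significant = !is.na(p_corr) & p_corr < 0.05,
                    tested = tested)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- rng_seed
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}
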