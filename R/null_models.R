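#' Shuffle tip identities of a distance matrix
#'
#' Applies one random permutation jointly to rows and columns while keeping
#' the original labels in place: taxa swap positions on the tree, the
#' community matrix is untouched. This is the randomization behind betaNTI
#' and betaNRI; it fixes observed alpha- and beta-diversity.
#'
#' @param dmat Symmetric distance matrix.
#' @param perm Optional explicit permutation (integer vector) for testing;
#'   default is a uniform random permutation from the current RNG.
#' @return Distance matrix with identical labels but shuffled structure.
#' @export
shuffle_tips <- function(dmat, perm = NULL) {
  check_dmat(dmat)
  n <- nrow(dmat)
  if (is.null(perm)) perm <- sample.int(n)
  if (!identical(sort(perm), seq_len(n))) stop("invalid permutation")
  out <- dmat[perm, perm, drop = FALSE]
  dimnames(out) <- dimnames(dmat)
  out
}

# Shared engine for betaNTI / betaNRI. One tip shuffle per null run is
# shared by all sample pairs; deviations with null sd < 1e-10 are flagged
# undefined (NA) rather than +-Inf.
beta_deviation <- function(cm, dmat, metric = c("bmntd", "bmpd"),
                           n_null = 1000, rng_seed = NULL, pool = NULL,
                           abundance_weighted = TRUE) {
  metric <- match.arg(metric)
  if (n_null < 99) stop("n_null must be >= 99")
  cm <- check_community(cm)
  if (!is.null(pool)) {
    missing_s <- setdiff(pool, colnames(cm))
    if (length(missing_s)) stop("pool samples not in community: ",
                                paste(missing_s, collapse = ", "))
    cm <- cm[, pool, drop = FALSE]
  }
  cm <- cm[rowSums(cm) > 0, , drop = FALSE]  # pool universe: observed taxa
  dmat <- dmat[rownames(cm), rownames(cm)]
  cm <- align_cm_dmat(cm, dmat)
  F <- relative_abundance(cm, abundance_weighted)
  fun <- if (metric == "bmntd") bmntd_matrix
         else function(F, d) crossprod(F, d %*% F)
  obs <- fun(F, dmat)
  ns <- ncol(F)
  s1 <- matrix(0, ns, ns); s2 <- matrix(0, ns, ns)
  with_seed(rng_seed, {
    for (r in seq_len(n_null)) {
      dp <- dmat[perm <- sample.int(nrow(dmat)), perm, drop = FALSE]
      nullval <- fun(F, dp)
      s1 <- s1 + nullval
      s2 <- s2 + nullval^2
    }
  })
  mu <- s1 / n_null
  va <- (s2 - n_null * mu^2) / (n_null - 1)
  sdev <- sqrt(pmax(va, 0))
  defined <- sdev > 1e-10
  dev <- ifelse(defined, (obs - mu) / sdev, NA_real_)
  dev <- (dev + t(dev)) / 2
  diag(dev) <- NA_real_
  dimnames(dev) <- dimnames(mu) <- dimnames(sdev) <-
    list(colnames(cm), colnames(cm))
  n_undef <- sum(!defined[upper.tri(defined)])
  if (n_undef > 0)
    message(sprintf("%d pair(s) with null sd ~ 0 flagged undefined", n_undef))
  structure(list(deviation = dev, obs = obs, null_mean = mu, null_sd = sdev,
                 metric = if (metric == "bmntd") "betaNTI" else "betaNRI",
                 n_null = n_null, seed = rng_seed,
                 n_undefined = n_undef),
            class = "beta_deviation")
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of abundance-weighted [beta_mntd()] against a
#' tip-shuffling null: `betaNTI = (obs - null mean) / null sd` per sample
#' pair. One tip shuffle per null run is shared across all pairs, matching
#' a whole-data-set randomization. Values < -2 indicate homogeneous
#' selection; values > +2 indicate variable selection (the +-2 thresholds
#' approximate the +-1.96 two-sided 5% points of each null distribution,
#' see [deviation_threshold()]).
#'
#' @param cm Community matrix (taxa x samples).
#' @param dmat Patristic distance matrix covering at least the taxa of
#'   `cm`.
#' @param n_null Number of tip shuffles (default 1000).
#' @param rng_seed Optional integer seed.
#' @param pool Optional character vector of sample IDs defining the species
#'   pool: the analysis is restricted to these samples and the shuffle
#'   universe to their observed taxa (e.g. low-N and high-N pools
#'   randomized separately). Default: all samples.
#' @param abundance_weighted Weight by relative abundances (default).
#' @return Object of class `"beta_deviation"`: matrices `deviation`
#'   (betaNTI), `obs`, `null_mean`, `null_sd`, plus `n_null`, `seed`,
#'   `n_undefined`.
#' @export
beta_nti <- function(cm, dmat, n_null = 1000, rng_seed = NULL, pool = NULL,
                     abundance_weighted = TRUE) {
  beta_deviation(cm, dmat, "bmntd", n_null, rng_seed, pool,
                 abundance_weighted)
}

#' Beta net relatedness index (betaNRI)
#'
#' As [beta_nti()] but standardizing [beta_mpd()], the "basal" metric, so
#' the index responds to turnover across deep clades.
#'
#' @inheritParams beta_nti
#' @return Object of class `"beta_deviation"` with `deviation` = betaNRI.
#' @export
beta_nri <- function(cm, dmat, n_null = 1000, rng_seed = NULL, pool = NULL,
                     abundance_weighted = TRUE) {
  beta_deviation(cm, dmat, "bmpd", n_null, rng_seed, pool,
                 abundance_weighted)
}

#' @export
print.beta_deviation <- function(x, ...) {
  v <- upper_vec(x$deviation)
  cat(sprintf("%s over %d samples (%d pairs, %d null runs)\n", x$metric,
              nrow(x$deviation), length(v), x$n_null))
  cat(sprintf("  mean %.3f, sd %.3f, %d undefined pair(s)\n",
              mean(v, na.rm = TRUE), sd(v, na.rm = TRUE), x$n_undefined))
  invisible(x)
}

# Pairwise Bray-Curtis on a taxa x samples matrix.
bray_curtis_matrix <- function(x) {
  ns <- ncol(x)
  tot <- colSums(x)
  if (any(tot <= 0)) stop("empty sample(s): ",
                          paste(colnames(x)[tot <= 0], collapse = ", "))
  out <- matrix(0, ns, ns, dimnames = list(colnames(x), colnames(x)))
  for (j in seq_len(ns - 1L)) for (k in (j + 1L):ns) {
    bc <- 1 - 2 * sum(pmin(x[, j], x[, k])) / (tot[j] + tot[k])
    out[j, k] <- out[k, j] <- bc
  }
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(j,k) = 1 - 2 sum_i min(x_ij, x_ik) / (sum_i x_ij + sum_i x_ik)`.
#'
#' @param cm Community matrix (taxa x samples) with non-empty samples.
#' @return Symmetric samples x samples matrix in \[0, 1\].
#' @export
bray_curtis <- function(cm) {
  cm <- check_community(cm, require_positive_samples = TRUE)
  bray_curtis_matrix(cm)
}

#' Species-pool statistics for the Raup-Crick null
#'
#' Occurrence frequency (number of samples occupied) and total abundance
#' per taxon, restricted to taxa observed in the pool. These two vectors
#' fully parameterize the null reassembly.
#'
#' @param cm Community matrix (taxa x samples) defining the pool.
#' @return List of class `"rc_pool_stats"` with `taxa`, `occ_freq`,
#'   `abund`.
#' @export
rc_pool_stats <- function(cm) {
  cm <- check_community(cm)
  keep <- rowSums(cm) > 0
  cm <- cm[keep, , drop = FALSE]
  structure(list(taxa = rownames(cm), occ_freq = rowSums(cm > 0),
                 abund = rowSums(cm)),
            class = "rc_pool_stats")
}

# Draw one null community: occupancy by occurrence frequency without
# replacement until the observed richness, then the observed total number
# of individuals across the drawn taxa (1 each, remainder multinomial by
# pool relative abundance) so richness is preserved exactly.
rc_null_sample <- function(stats, richness, total) {
  npool <- length(stats$taxa)
  if (richness > npool)
    stop("sample richness exceeds species-pool size")
  drawn <- sample.int(npool, richness, prob = stats$occ_freq)
  counts <- rep(1L, richness)
  if (total > richness)
    counts <- counts + rmultinom(1L, total - richness,
                                 stats$abund[drawn])[, 1L]
  out <- numeric(npool)
  out[drawn] <- counts
  out
}

#' Draw communities from the Raup-Crick null model
#'
#' Generates whole communities by the same two-phase procedure the RC-bray
#' null uses (occupancy by occurrence frequency without replacement up to
#' the requested richness, then the requested total distributed over the
#' drawn taxa by pool relative abundance with one individual guaranteed
#' each). Useful for calibration studies: RC-bray evaluated on pairs
#' generated this way, against the same pool statistics, is approximately
#' uniform on \[-1, 1\].
#'
#' @param pool_stats A [rc_pool_stats()] object.
#' @param richness Integer vector: taxa per generated community.
#' @param totals Integer vector: individuals per generated community
#'   (recycled against `richness`).
#' @param rng_seed Optional integer seed.
#' @return Community matrix (pool taxa x generated samples).
#' @export
rc_null_communities <- function(pool_stats, richness, totals,
                                rng_seed = NULL) {
  stopifnot(inherits(pool_stats, "rc_pool_stats"))
  n <- max(length(richness), length(totals))
  richness <- rep_len(richness, n)
  totals <- rep_len(totals, n)
  if (any(totals < richness)) stop("totals must be >= richness")
  with_seed(rng_seed, {
    out <- vapply(seq_len(n), function(s)
      rc_null_sample(pool_stats, richness[s], totals[s]),
      numeric(length(pool_stats$taxa)))
    dimnames(out) <- list(pool_stats$taxa, sprintf("null%03d", seq_len(n)))
    out
  })
}

#' Bray-Curtis Raup-Crick null model (RC-bray)
#'
#' Compares each pair's observed Bray-Curtis dissimilarity against a null
#' in which every sample is reassembled from the species pool: taxa are
#' drawn without replacement with probability proportional to their pool
#' occurrence frequency until the observed richness is reached, then the
#' observed number of individuals is distributed over the drawn taxa with
#' probability proportional to pool relative abundance (each drawn taxon
#' receives at least one individual, preserving richness). With `n_below`
#' and `n_equal` the counts of null dissimilarities below/equal to the
#' observed value, `RC_bray = 2 ((n_below + n_equal / 2) / n_null) - 1`,
#' bounded in \[-1, 1\]. RC_bray > +0.95 marks more turnover than expected
#' under drift alone, RC_bray < -0.95 less.
#'
#' @param cm Community matrix of non-negative integer counts
#'   (taxa x samples). Non-integer abundances are an error: round or
#'   rescale to counts first.
#' @param n_null Number of null reassemblies (default 999). One reassembly
#'   of every sample per run is shared across pairs.
#' @param rng_seed Optional integer seed.
#' @param pool Optional character vector of sample IDs: the analysis and
#'   the pool statistics are restricted to these samples.
#' @param pool_stats Optional [rc_pool_stats()] object overriding the pool
#'   statistics estimated from the data (advanced; used e.g. in
#'   calibration studies where observed and null communities must share
#'   one generating pool). Taxa of `cm` must be a subset of its taxa.
#' @return Object of class `"raup_crick"`: matrices `rc` and `bray`,
#'   counts `n_below`/`n_equal`, plus `n_null` and `seed`.
#' @export
raup_crick_bray <- function(cm, n_null = 999, rng_seed = NULL, pool = NULL,
                            pool_stats = NULL) {
  if (n_null < 99) stop("n_null must be >= 99")
  cm <- check_community(cm, require_positive_samples = TRUE)
  if (max(abs(cm - round(cm))) > 1e-8)
    stop("RC-bray needs integer counts; round or rescale abundances first")
  cm <- round(cm)
  if (!is.null(pool)) {
    missing_s <- setdiff(pool, colnames(cm))
    if (length(missing_s)) stop("pool samples not in community: ",
                                paste(missing_s, collapse = ", "))
    cm <- cm[, pool, drop = FALSE]
  }
  if (is.null(pool_stats)) {
    stats <- rc_pool_stats(cm)
    cm <- cm[stats$taxa, , drop = FALSE]
  } else {
    stopifnot(inherits(pool_stats, "rc_pool_stats"))
    stats <- pool_stats
    extra <- setdiff(rownames(cm)[rowSums(cm) > 0], stats$taxa)
    if (length(extra)) stop("taxa absent from pool_stats: ",
                            paste(head(extra, 5L), collapse = ", "))
    full <- matrix(0, length(stats$taxa), ncol(cm),
                   dimnames = list(stats$taxa, colnames(cm)))
    shared <- intersect(rownames(cm), stats$taxa)
    full[shared, ] <- cm[shared, ]
    cm <- full
  }
  ns <- ncol(cm)
  richness <- colSums(cm > 0)
  totals <- colSums(cm)
  obs <- bray_curtis_matrix(cm)
  below <- matrix(0L, ns, ns); equal <- matrix(0L, ns, ns)
  with_seed(rng_seed, {
    for (r in seq_len(n_null)) {
      nullcm <- vapply(seq_len(ns), function(s)
        rc_null_sample(stats, richness[s], totals[s]),
        numeric(length(stats$taxa)))
      nullbc <- bray_curtis_matrix(nullcm)
      below <- below + (nullbc < obs - 1e-10)
      equal <- equal + (abs(nullbc - obs) <= 1e-10)
    }
  })
  rc <- 2 * ((below + equal / 2) / n_null) - 1
  diag(rc) <- NA_real_
  dimnames(rc) <- dimnames(below) <- dimnames(equal) <- dimnames(obs)
  structure(list(rc = rc, bray = obs, n_below = below, n_equal = equal,
                 n_null = n_null, seed = rng_seed),
            class = "raup_crick")
}

#' @export
print.raup_crick <- function(x, ...) {
  v <- upper_vec(x$rc)
  cat(sprintf("RC-bray over %d samples (%d pairs, %d null runs)\n",
              nrow(x$rc), length(v), x$n_null))
  cat(sprintf("  mean %.3f, %.1f%% of pairs with |RC| > 0.95\n",
              mean(v), 100 * mean(abs(v) > 0.95)))
  invisible(x)
}

#' Long-format export of pairwise null-model results
#'
#' @param x A `"beta_deviation"` or `"raup_crick"` object.
#' @return data.frame with one row per unordered sample pair.
#' @export
pair_table <- function(x) {
  m <- if (inherits(x, "beta_deviation")) x$deviation
       else if (inherits(x, "raup_crick")) x$rc
       else stop("unsupported object")
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- data.frame(sample_i = rownames(m)[idx[, 1L]],
                    sample_j = colnames(m)[idx[, 2L]],
                    stringsAsFactors = FALSE)
  if (inherits(x, "beta_deviation")) {
    out$metric <- x$metric
    out$obs <- x$obs[idx]
    out$null_mean <- x$null_mean[idx]
    out$null_sd <- x$null_sd[idx]
    out$deviation <- x$deviation[idx]
  } else {
    out$bray <- x$bray[idx]
    out$rc <- x$rc[idx]
  }
  out
}
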