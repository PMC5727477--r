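#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the path between tips i
#' and j. Rows/columns follow the tree's tip-label order.
#'
#' @param tree A validated `"phylo"` tree.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  d <- cophenetic(tree)
  d <- d[tree$tip.label, tree$tip.label]
  # cophenetic computes each entry once; enforce exact symmetry anyway
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  d
}

# Edge x tip incidence: TRUE when the tip descends from (is below) the edge.
# Used by faith_pd / ses_pd to vectorize PD over samples and null runs.
edge_tip_incidence <- function(tree) {
  ntip <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  inc <- below[tr$edge[, 2L], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  list(incidence = inc, lengths = tr$edge.length)
}

#' Faith's phylogenetic diversity per sample
#'
#' PD of a sample is the total branch length of the minimal rooted subtree
#' spanning the root and all taxa present (abundance > 0). The path to the
#' root is included, so a single-tip sample has PD equal to that tip's
#' root-to-tip distance.
#'
#' @param cm Community matrix (taxa x samples), taxa matching the tree tips.
#' @param tree A validated `"phylo"` tree.
#' @return Named numeric vector of PD values; samples with zero richness
#'   get `NA` with a warning.
#' @export
faith_pd <- function(cm, tree) {
  validate_tree(tree)
  cm <- check_community(cm)
  if (!setequal(rownames(cm), tree$tip.label))
    stop("community taxa and tree tips differ; run align_tree_and_table()")
  et <- edge_tip_incidence(tree)
  pres <- (cm[colnames(et$incidence), , drop = FALSE] > 0) * 1
  covered <- (et$incidence %*% pres) > 0
  pd <- as.numeric(crossprod(covered, et$lengths))
  names(pd) <- colnames(cm)
  empty <- colSums(pres) == 0
  if (any(empty)) {
    warning("sample(s) with zero richness: PD undefined for ",
            paste(names(pd)[empty], collapse = ", "))
    pd[empty] <- NA_real_
  }
  pd
}

#' Standardized effect size of Faith's PD under a tip-shuffle null
#'
#' The null distribution is obtained by shuffling tip labels on the tree
#' (equivalently, permuting which taxa the sample's presences map to) and
#' recomputing PD; `ses.PD = (obs - null mean) / null sd`. A two-tailed
#' rank p-value is reported per sample. Null standard deviations below
#' 1e-10 (e.g. a sample containing every taxon) are flagged undefined
#' rather than propagated as infinities.
#'
#' @param cm Community matrix (taxa x samples).
#' @param tree A validated `"phylo"` tree.
#' @param n_null Number of null shuffles (>= 99).
#' @param rng_seed Optional integer seed.
#' @return A data.frame with columns `sample_id`, `pd_obs`, `null_mean`,
#'   `null_sd`, `ses_pd`, `p`, `defined`; attributes `n_null` and `seed`.
#' @export
ses_pd <- function(cm, tree, n_null = 999, rng_seed = NULL) {
  if (n_null < 99) stop("n_null must be >= 99")
  validate_tree(tree)
  cm <- check_community(cm)
  if (!setequal(rownames(cm), tree$tip.label))
    stop("community taxa and tree tips differ; run align_tree_and_table()")
  et <- edge_tip_incidence(tree)
  pres <- (cm[colnames(et$incidence), , drop = FALSE] > 0) * 1
  obs <- as.numeric(crossprod((et$incidence %*% pres) > 0, et$lengths))
  ntax <- nrow(pres)
  nulls <- with_seed(rng_seed, {
    vapply(seq_len(n_null), function(r) {
      perm <- sample.int(ntax)
      as.numeric(crossprod((et$incidence %*% pres[perm, , drop = FALSE]) > 0,
                           et$lengths))
    }, numeric(ncol(pres)))
  })
  nulls <- matrix(nulls, nrow = ncol(pres))  # samples x runs
  mu <- rowMeans(nulls)
  sdev <- apply(nulls, 1L, sd)
  defined <- sdev > 1e-10 & colSums(pres) > 0
  ses <- ifelse(defined, (obs - mu) / sdev, NA_real_)
  n_le <- rowSums(nulls <= obs + 1e-12)
  n_ge <- rowSums(nulls >= obs - 1e-12)
  p <- pmin(1, 2 * (pmin(n_le, n_ge) + 1) / (n_null + 1))
  p[!defined] <- NA_real_
  out <- data.frame(sample_id = colnames(cm), pd_obs = obs, null_mean = mu,
                    null_sd = sdev, ses_pd = ses, p = p, defined = defined,
                    stringsAsFactors = FALSE)
  attr(out, "n_null") <- n_null
  attr(out, "seed") <- rng_seed
  out
}

# Core of betaMNTD: M[i, k] = min over taxa present in sample k of d(i, .).
# betaMNTD = (t(F) M + t(M) F) / 2 restricted to its sample-pair entries.
bmntd_matrix <- function(F, dmat) {
  ns <- ncol(F)
  M <- matrix(NA_real_, nrow(F), ns)
  for (k in seq_len(ns)) {
    idx <- which(F[, k] > 0)
    m <- dmat[, idx[1L]]
    for (j in idx[-1L]) m <- pmin(m, dmat[, j])
    M[, k] <- m
  }
  A <- crossprod(F, M)
  out <- (A + t(A)) / 2
  dimnames(out) <- list(colnames(F), colnames(F))
  diag(out) <- diag(A)  # within-sample value uses its own minima
  out
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For samples j and k,
#' `betaMNTD(j,k) = 1/2 * (sum_i f_ij min_i' d(i,i') + sum_i' f_i'k min_i d(i',i))`
#' where the minima run over taxa present in the other sample and f are
#' within-sample relative abundances (uniform over present taxa when
#' `abundance_weighted = FALSE`). A "terminal" turnover metric: it reflects
#' distances between closest relatives.
#'
#' @param cm Community matrix (taxa x samples).
#' @param dmat Patristic distance matrix over the same taxa.
#' @param abundance_weighted Weight by relative abundance (default) or
#'   presence.
#' @return Symmetric samples x samples matrix (diagonal: within-sample
#'   nearest-taxon value, 0 when taxa match themselves).
#' @export
beta_mntd <- function(cm, dmat, abundance_weighted = TRUE) {
  cm <- align_cm_dmat(cm, dmat)
  F <- relative_abundance(cm, abundance_weighted)
  bmntd_matrix(F, dmat)
}

#' Between-community mean pairwise distance (betaMPD)
#'
#' `betaMPD(j,k) = sum_i sum_i' f_ij f_i'k d(i,i')`, the abundance-weighted
#' mean of all cross-community pairwise phylogenetic distances. A "basal"
#' turnover metric dominated by deep branches.
#'
#' @inheritParams beta_mntd
#' @return Symmetric samples x samples matrix.
#' @export
beta_mpd <- function(cm, dmat, abundance_weighted = TRUE) {
  cm <- align_cm_dmat(cm, dmat)
  F <- relative_abundance(cm, abundance_weighted)
  out <- crossprod(F, dmat %*% F)
  out <- (out + t(out)) / 2
  dimnames(out) <- list(colnames(cm), colnames(cm))
  out
}

#' Write a square matrix as TSV with an ID header column
#'
#' @param m Square matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
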