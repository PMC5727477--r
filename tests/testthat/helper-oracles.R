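# Shared fixtures and independent brute-force oracles used across tests.
# The oracles deliberately use naive per-pair enumeration so they share no
# code path with the package implementations they check.

micro_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# Community on the micro tree: columns j = {A, B}, k = {C, D}.
micro_cm <- function() {
  cm <- matrix(0, 4, 2, dimnames = list(c("A", "B", "C", "D"), c("j", "k")))
  cm[c("A", "B"), "j"] <- 1
  cm[c("C", "D"), "k"] <- 1
  cm
}

# Patristic distances by explicit node-path walking.
bf_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2L]] <- tree$edge.length
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    path <- ape::nodepath(tree, i, j)
    # every node on the path contributes the edge above it, except the
    # node nearest the root (the path's apex)
    d[i, j] <- d[j, i] <- sum(elen[setdiff(path, deepest_node(tree, path))])
  }
  d
}

# The node on `path` closest to the root (smallest depth).
deepest_node <- function(tree, path) {
  depths <- ape::node.depth.edgelength(tree)
  path[which.min(depths[path])]
}

# Nearest-taxon beta diversity by direct evaluation of the formula.
bf_bmntd <- function(cm, d, weighted = TRUE) {
  ns <- ncol(cm)
  out <- matrix(0, ns, ns, dimnames = list(colnames(cm), colnames(cm)))
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    if (a == b) next
    pa <- rownames(cm)[cm[, a] > 0]
    pb <- rownames(cm)[cm[, b] > 0]
    fa <- if (weighted) cm[pa, a] / sum(cm[, a]) else rep(1 / length(pa), length(pa))
    fb <- if (weighted) cm[pb, b] / sum(cm[, b]) else rep(1 / length(pb), length(pb))
    t1 <- sum(vapply(seq_along(pa), function(i)
      fa[i] * min(d[pa[i], pb]), numeric(1)))
    t2 <- sum(vapply(seq_along(pb), function(i)
      fb[i] * min(d[pb[i], pa]), numeric(1)))
    out[a, b] <- (t1 + t2) / 2
  }
  (out + t(out)) / 2
}

# Mean pairwise beta diversity by direct double sum.
bf_bmpd <- function(cm, d, weighted = TRUE) {
  ns <- ncol(cm)
  out <- matrix(0, ns, ns, dimnames = list(colnames(cm), colnames(cm)))
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    pa <- rownames(cm)[cm[, a] > 0]
    pb <- rownames(cm)[cm[, b] > 0]
    fa <- if (weighted) cm[pa, a] / sum(cm[, a]) else rep(1 / length(pa), length(pa))
    fb <- if (weighted) cm[pb, b] / sum(cm[, b]) else rep(1 / length(pb), length(pb))
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb))
      s <- s + fa[i] * fb[j] * d[pa[i], pb[j]]
    out[a, b] <- s
  }
  out
}

# Faith PD by unioning per-tip root paths and summing unique edges.
bf_pd <- function(cm, tree) {
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- ape::Ntip(tree) + 1L
  vapply(seq_len(ncol(cm)), function(s) {
    tips <- which(cm[, s] > 0)
    if (length(tips) == 0L) return(NA_real_)
    nodes <- unique(unlist(lapply(tips, function(tp)
      ape::nodepath(tree, root, tp))))
    sum(elen[setdiff(nodes, root)])
  }, numeric(1))
}

# Bray-Curtis by direct formula.
bf_bray <- function(cm) {
  ns <- ncol(cm)
  out <- matrix(0, ns, ns, dimnames = list(colnames(cm), colnames(cm)))
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    num <- 2 * sum(pmin(cm[, a], cm[, b]))
    out[a, b] <- out[b, a] <- 1 - num / (sum(cm[, a]) + sum(cm[, b]))
  }
  out
}

# Random community over the tips of `tree`: every sample non-empty.
random_cm <- function(tree, n_samples, seed) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  repeat {
    cm <- matrix(rpois(n * n_samples, 1.2), n, n_samples,
                 dimnames = list(tree$tip.label,
                                 sprintf("s%02d", seq_len(n_samples))))
    if (all(colSums(cm) > 0)) return(cm)
  }
}
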