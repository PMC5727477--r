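# Internal validators shared across modules.

# Validate a community matrix: numeric, non-negative, unique taxon/sample
# names. Returns the matrix (possibly coerced from data.frame) invisibly.
check_community <- function(cm, require_positive_samples = FALSE) {
  if (is.data.frame(cm)) cm <- as.matrix(cm)
  if (!is.matrix(cm) || !is.numeric(cm))
    stop("community matrix must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(cm)) || is.null(colnames(cm)))
    stop("community matrix needs taxon rownames and sample colnames")
  if (anyDuplicated(rownames(cm)))
    stop("duplicate taxon IDs in community matrix")
  if (anyDuplicated(colnames(cm)))
    stop("duplicate sample IDs in community matrix")
  if (anyNA(cm)) stop("community matrix contains missing values")
  if (any(cm < 0)) {
    idx <- which(cm < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 rownames(cm)[idx[1L]], colnames(cm)[idx[2L]]))
  }
  if (require_positive_samples && any(colSums(cm) <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(colnames(cm)[colSums(cm) <= 0], collapse = ", "))
  invisible(cm)
}

# Validate a square symmetric distance matrix with zero diagonal.
check_dmat <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("expected a square numeric distance matrix")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must carry identical row and column names")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal is not zero")
  invisible(d)
}

# Align a community matrix (taxa x samples) with a distance matrix over the
# same taxa; reorders cm rows to the distance matrix order.
align_cm_dmat <- function(cm, dmat) {
  cm <- check_community(cm)
  check_dmat(dmat)
  if (!setequal(rownames(cm), rownames(dmat)))
    stop("community taxa and distance-matrix taxa differ; ",
         "run align_tree_and_table() first")
  cm[rownames(dmat), , drop = FALSE]
}

# Relative abundances per sample; presence-based -> uniform over present taxa.
relative_abundance <- function(cm, abundance_weighted = TRUE) {
  if (!abundance_weighted) cm <- (cm > 0) * 1
  tot <- colSums(cm)
  if (any(tot <= 0)) stop("empty sample(s): ",
                          paste(colnames(cm)[tot <= 0], collapse = ", "))
  sweep(cm, 2L, tot, "/")
}

# Set the RNG state locally when a seed is supplied, restoring it on exit so
# seeded calls do not disturb the caller's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Upper-triangle vector of a square matrix (row < col order).
upper_vec <- function(m) m[upper.tri(m)]
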