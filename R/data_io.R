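#' Read and validate a rooted phylogenetic tree
#'
#' Reads a newick tree and enforces the invariants required by all
#' downstream analyses: a rooted topology, unique non-empty tip labels, and
#' a branch length on every edge. Zero-length branches are allowed with a
#' warning (they collapse nearest-taxon distances); negative or missing
#' lengths are hard errors.
#'
#' @param path Path to a newick file. Quoted labels are allowed.
#' @return An [ape::read.tree()] `"phylo"` object that passed validation.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,(C:1,D:1):1);", tf)
#' tr <- read_tree(tf)
#' ape::Ntip(tr)
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in ", path)
  validate_tree(tr)
  message(sprintf("read tree with %d tips from %s", ape::Ntip(tr), path))
  tr
}

#' Validate a phylogenetic tree object
#'
#' Checks the invariants assumed throughout the package. Called by
#' [read_tree()] and by every function consuming a tree directly.
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly; errors describe the first violation found.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty tip label(s)")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; all edges need a length")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1L]
    child <- tree$edge[bad, 2L]
    lab <- if (child <= ape::Ntip(tree)) tree$tip.label[child]
           else paste0("internal node ", child)
    stop("missing branch length on the edge leading to ", lab)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length(s)")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; a rooted tree is required")
  if (any(tree$edge.length == 0))
    warning("tree contains zero-length branches; ",
            "nearest-taxon distances may collapse")
  invisible(tree)
}

#' Write a tree to newick
#'
#' @param tree A validated `"phylo"` object.
#' @param path Output path.
#' @return `path`, invisibly. Branch lengths are written with 15 significant
#'   digits so patristic distances round-trip to numerical precision.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Read a community abundance table
#'
#' Reads a TSV with taxa as rows and samples as columns (header row of
#' sample IDs, first column taxon IDs). Cells are non-negative counts or
#' relative abundances. Zero-only taxa are retained; filtering is explicit
#' via [filter_rare()]. Samples with zero total are accepted with a warning
#' since some analyses tolerate them and others check again.
#'
#' @param path Path to a tab-separated table.
#' @return Numeric matrix, taxa x samples, with dimnames.
#' @export
read_community <- function(path) {
  if (!file.exists(path)) stop("community table not found: ", path)
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df, 2L, as.numeric))),
                 arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric cell at taxon '%s', sample '%s'",
                   rownames(df)[bad[1L, 1L]], colnames(df)[bad[1L, 2L]]))
    stop("community table is not numeric")
  }
  check_community(m)
  if (any(colSums(m) == 0))
    warning("sample(s) with zero total abundance: ",
            paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  message(sprintf("read community table: %d taxa x %d samples",
                  nrow(m), ncol(m)))
  m
}

#' Write a community table to TSV
#'
#' @param cm Community matrix (taxa x samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community <- function(cm, path) {
  cm <- check_community(cm)
  df <- data.frame(taxon = rownames(cm), cm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' One row per sample. The first column (or a column named `sample_id`) is
#' taken as the sample identifier.
#'
#' @param path Path to a tab-separated table.
#' @return A data.frame with a `sample_id` character column.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in metadata")
  df
}

#' Remove rare taxa from a community table
#'
#' Two independent filters used for amplicon data: an occupancy filter that
#' drops taxa present (abundance > 0) in fewer than `min_occupancy` samples,
#' and a mean-relative-abundance filter that drops taxa whose arithmetic
#' mean relative abundance across all samples (zeros included) is below
#' `min_mean_rel_abund`. Either threshold can be set to 0 to disable it.
#'
#' @param cm Community matrix (taxa x samples).
#' @param min_occupancy Integer; minimum number of samples a taxon must
#'   occur in. Taxa occurring in fewer are removed.
#' @param min_mean_rel_abund Fraction in \[0, 1\]; taxa with mean relative
#'   abundance strictly below this are removed (e.g. `1e-4` for 0.01%).
#' @return Filtered community matrix; removal counts are reported via
#'   `message()`.
#' @export
#' @examples
#' cm <- matrix(c(5, 0, 0, 4, 0, 1, 3, 2, 6), nrow = 3,
#'              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
#' filter_rare(cm, min_occupancy = 2)
filter_rare <- function(cm, min_occupancy = 0, min_mean_rel_abund = 0) {
  cm <- check_community(cm)
  if (min_occupancy < 0 || min_mean_rel_abund < 0)
    stop("thresholds must be non-negative")
  occupancy <- rowSums(cm > 0)
  tot <- colSums(cm)
  rel <- sweep(cm, 2L, ifelse(tot > 0, tot, 1), "/")
  mean_rel <- rowMeans(rel)
  drop_occ <- occupancy < min_occupancy
  drop_rel <- mean_rel < min_mean_rel_abund
  keep <- !(drop_occ | drop_rel)
  if (!any(keep)) stop("all taxa removed; community would be empty")
  if (any(!keep))
    message(sprintf(
      "filter_rare: removed %d of %d taxa (%d by occupancy < %s, %d by mean relative abundance < %s)",
      sum(!keep), nrow(cm), sum(drop_occ), format(min_occupancy),
      sum(drop_rel), format(min_mean_rel_abund)))
  cm[keep, , drop = FALSE]
}

#' Reconcile a tree and a community table
#'
#' Prunes the tree to the taxa present in the table and restricts the table
#' to tips of the tree, reporting what was dropped on each side. Row order
#' of the returned table follows the pruned tree's tip order.
#'
#' @param tree A validated `"phylo"` object.
#' @param cm Community matrix (taxa x samples).
#' @return A list with elements `tree` and `community`.
#' @export
align_tree_and_table <- function(tree, cm) {
  validate_tree(tree)
  cm <- check_community(cm)
  shared <- intersect(tree$tip.label, rownames(cm))
  if (length(shared) == 0L)
    stop("no taxa shared between tree and community table")
  drop_tree <- setdiff(tree$tip.label, shared)
  drop_cm <- setdiff(rownames(cm), shared)
  if (length(drop_tree))
    message(sprintf("align: dropped %d tip(s) absent from table", length(drop_tree)))
  if (length(drop_cm))
    message(sprintf("align: dropped %d taxon row(s) absent from tree", length(drop_cm)))
  tr <- if (length(drop_tree)) ape::keep.tip(tree, shared) else tree
  list(tree = tr, community = cm[tr$tip.label, , drop = FALSE])
}
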