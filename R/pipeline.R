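# End-to-end orchestration of the two study designs: a spatial gradient
# (press) analysis and a closed-system pulse time-series analysis.

write_outputs <- function(out_dir, tables, json, manifest_lines) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    write.table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(json))
    jsonlite::write_json(json[[nm]], file.path(out_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  writeLines(manifest_lines, file.path(out_dir, "run_manifest.txt"))
  invisible(out_dir)
}

# Segmented fit that degrades to NULL (with a message) when a segment
# lacks enough points, e.g. a single-level gradient.
try_seg <- function(x, y, breakpoint, rng_seed, what) {
  tryCatch(segmented_fit(x, y, breakpoint, rng_seed = rng_seed),
           error = function(e) {
             message(what, ": segmented fit skipped (", e$message, ")")
             NULL
           })
}

seg_summary <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(breakpoint = fit$breakpoint,
       low = fit$low[c("slope", "intercept", "r_squared", "p", "n")],
       high = fit$high[c("slope", "intercept", "r_squared", "p", "n")])
}

#' Run the spatial-gradient (press) analysis
#'
#' On communities sampled along a numeric environmental gradient (e.g. N
#' deposition rates): computes ses.PD per sample with a segmented fit
#' against the gradient; betaNTI and betaNRI with a whole-data-set species
#' pool; and segmented fits of betaNRI against ln absolute gradient
#' differences (between-level pairs) and against the raw gradient value
#' (within-level pairs). Every stage derives its seed from `rng_seed`, so
#' reruns are identical.
#'
#' @param tree Rooted tree covering the community taxa.
#' @param community Community matrix (taxa x samples).
#' @param metadata data.frame with `sample_id` and the gradient column.
#' @param axis_col Name of the numeric gradient column (default "N_rate").
#' @param n_null Null runs for ses.PD/betaNTI/betaNRI (default 1000).
#' @param breakpoint Gradient value splitting the segmented fits
#'   (default 10.5).
#' @param rng_seed Integer master seed (default 1).
#' @param out_dir Optional output directory for TSV/JSON artifacts and a
#'   run manifest.
#' @return List with `ses_pd`, `ses_pd_fit`, `bnti`, `bnri`, `pairs`
#'   (per-pair table with gradient differences), `bnri_between_fit`,
#'   `bnri_within_fit`.
#' @export
run_gradient_pipeline <- function(tree, community, metadata,
                                  axis_col = "N_rate", n_null = 1000,
                                  breakpoint = 10.5, rng_seed = 1,
                                  out_dir = NULL) {
  if (!axis_col %in% names(metadata))
    stop("metadata lacks column '", axis_col, "'")
  al <- align_tree_and_table(tree, community)
  tree <- al$tree; cm <- al$community
  meta <- metadata[match(colnames(cm), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  axis <- setNames(as.numeric(meta[[axis_col]]), meta$sample_id)
  if (anyNA(axis)) stop("non-numeric gradient values")
  dmat <- patristic_distances(tree)

  sp <- ses_pd(cm, tree, n_null = n_null, rng_seed = rng_seed + 101L)
  sp_fit <- try_seg(axis[sp$sample_id], sp$ses_pd, breakpoint,
                    rng_seed + 102L, "ses.PD vs gradient")

  bnti <- beta_nti(cm, dmat, n_null = n_null, rng_seed = rng_seed + 103L)
  bnri <- beta_nri(cm, dmat, n_null = n_null, rng_seed = rng_seed + 104L)

  tab <- pair_table(bnri)
  tab$bnti <- pair_table(bnti)$deviation
  names(tab)[names(tab) == "deviation"] <- "bnri"
  tab$axis_i <- axis[tab$sample_i]
  tab$axis_j <- axis[tab$sample_j]
  tab$delta <- abs(tab$axis_i - tab$axis_j)
  tab$between_level <- tab$delta > 0

  between_fit <- NULL
  if (length(unique(axis)) < 2) {
    warning("single gradient level: between-level analyses skipped")
  } else {
    bt <- tab[tab$between_level, ]
    between_fit <- try_seg(log(bt$delta), bt$bnri, log(breakpoint),
                           rng_seed + 105L, "betaNRI between levels")
  }
  within_fit <- NULL
  wt <- tab[!tab$between_level, ]
  if (nrow(wt) >= 6) {
    within_fit <- try_seg(wt$axis_i, wt$bnri, breakpoint,
                          rng_seed + 106L, "betaNRI within levels")
  }

  res <- list(ses_pd = sp, ses_pd_fit = sp_fit, bnti = bnti, bnri = bnri,
              pairs = tab, bnri_between_fit = between_fit,
              bnri_within_fit = within_fit)
  write_outputs(out_dir,
    tables = list(ses_pd = sp,
                  pairs = tab[, c("sample_i", "sample_j", "bnti", "bnri",
                                  "delta", "between_level")]),
    json = list(gradient_summary = list(
      seed = rng_seed, n_null = n_null, axis = axis_col,
      breakpoint = breakpoint,
      ses_pd_fit = seg_summary(sp_fit),
      bnri_between_fit = seg_summary(between_fit),
      bnri_within_fit = seg_summary(within_fit))),
    manifest_lines = c(
      "assemblage gradient pipeline",
      sprintf("samples: %d  taxa: %d", ncol(cm), nrow(cm)),
      sprintf("axis: %s  breakpoint: %g", axis_col, breakpoint),
      sprintf("n_null: %d  seed: %d", n_null, rng_seed)))
  res
}

#' Run the pulse time-series (closed-system) analysis
#'
#' On activity profiles sampled through time after a pulse disturbance,
#' with one or more species pools (e.g. soils with different nutrient
#' histories) analysed separately: per pool, betaNTI and RC-bray with the
#' pool restricted to that pool's samples, the seven-category process
#' classification with `dispersal_possible = FALSE` by default (closed
#' microcosms, so low compositional turnover marks weak homogeneous
#' selection rather than homogenizing dispersal), a Mantel test of betaNTI
#' against ln absolute time differences, and a Monte Carlo test of the
#' mean betaNTI against zero. Pool dispersions (distance-to-centroid of
#' the betaNTI matrix) are compared pairwise by a permutation test.
#'
#' @param tree Rooted tree covering the community taxa.
#' @param community Community matrix (taxa x samples, integer counts).
#' @param metadata data.frame with `sample_id`, a numeric time column and
#'   a pool column.
#' @param time_col Name of the time column in hours (default "time_h").
#' @param pool_col Name of the pool/group column (default "group").
#' @param n_null Null runs for betaNTI (default 1000).
#' @param n_null_rc Null runs for RC-bray (default 999).
#' @param n_perm Permutations for the Mantel / Monte Carlo tests
#'   (default 10000).
#' @param dispersal_possible Classification flag (default `FALSE`).
#' @param rng_seed Integer master seed (default 1).
#' @param out_dir Optional output directory.
#' @return List with one element per pool (`bnti`, `rc`, `classification`,
#'   `mantel_time`, `mean_test`, `dispersion`) plus
#'   `dispersion_comparison`.
#' @export
run_pulse_pipeline <- function(tree, community, metadata,
                               time_col = "time_h", pool_col = "group",
                               n_null = 1000, n_null_rc = 999,
                               n_perm = 10000, dispersal_possible = FALSE,
                               rng_seed = 1, out_dir = NULL) {
  for (cc in c(time_col, pool_col))
    if (!cc %in% names(metadata)) stop("metadata lacks column '", cc, "'")
  al <- align_tree_and_table(tree, community)
  tree <- al$tree; cm <- al$community
  meta <- metadata[match(colnames(cm), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  times <- setNames(as.numeric(meta[[time_col]]), meta$sample_id)
  if (any(times <= 0)) stop("time values must be strictly positive")
  pools <- split(meta$sample_id, meta[[pool_col]])
  dmat <- patristic_distances(tree)

  res <- list()
  label_rows <- NULL
  frac_json <- list()
  k <- 0L
  for (pn in names(pools)) {
    k <- k + 1L
    ids <- pools[[pn]]
    if (length(ids) < 3) {
      warning("pool '", pn, "' has < 3 samples; skipped")
      next
    }
    bnti <- beta_nti(cm, dmat, n_null = n_null,
                     rng_seed = rng_seed + 200L + 10L * k, pool = ids)
    rc <- raup_crick_bray(cm, n_null = n_null_rc,
                          rng_seed = rng_seed + 201L + 10L * k, pool = ids)
    tab <- pair_table(bnti)
    rcv <- rc$rc[cbind(tab$sample_i, tab$sample_j)]
    lab <- classify_pairs(tab$deviation, rcv, dispersal_possible)
    cl <- list(pairs = data.frame(sample_i = tab$sample_i,
                                  sample_j = tab$sample_j,
                                  bnti = tab$deviation, rc = rcv,
                                  label = lab, stringsAsFactors = FALSE),
               fractions = if (any(lab != "undefined"))
                 process_fractions(lab, dispersal_possible) else NULL)
    dev_vals <- upper_vec(bnti$deviation)
    all_defined <- all(!is.na(dev_vals))
    mt <- mdt <- NULL
    if (sum(!is.na(dev_vals)) >= 3) {
      tmat <- ln_abs_diff(times[ids])
      mt <- tryCatch(
        mantel_test(bnti$deviation[ids, ids], tmat, n_perm = n_perm,
                    rng_seed = rng_seed + 202L + 10L * k),
        error = function(e) {
          message("pool '", pn, "': Mantel test skipped (", e$message, ")")
          NULL
        })
      mdt <- mean_deviation_test(dev_vals, n_perm = n_perm,
                                 rng_seed = rng_seed + 203L + 10L * k,
                                 group = pn)
    } else {
      message("pool '", pn, "': ", sum(is.na(dev_vals)),
              " undefined pair(s); Mantel and mean tests skipped")
    }
    disp <- if (all_defined) dispersion_to_centroid(bnti$deviation)
            else NULL
    res[[pn]] <- list(bnti = bnti, rc = rc, classification = cl,
                      mantel_time = mt, mean_test = mdt,
                      dispersion = disp)
    lr <- cl$pairs; lr$pool <- pn
    label_rows <- rbind(label_rows, lr)
    frac_json[[pn]] <- list(
      fractions = if (is.null(cl$fractions)) NULL
                  else as.list(cl$fractions$fractions),
      n_defined = sum(lab != "undefined"),
      n_undefined = sum(lab == "undefined"),
      mean_bnti = if (is.null(mdt)) NA else mdt$mean,
      sd_bnti = if (is.null(mdt)) NA else mdt$sd,
      mean_test_p = if (is.null(mdt)) NA else mdt$p,
      mantel_r = if (is.null(mt)) NA else mt$r,
      mantel_p = if (is.null(mt)) NA else mt$p)
  }
  if (length(res) == 0) stop("no pool with enough samples")

  comp <- NULL
  pool_names <- names(res)
  if (length(pool_names) >= 2) {
    comp <- list()
    for (a in seq_along(pool_names)[-length(pool_names)])
      for (b in (a + 1L):length(pool_names)) {
        pa <- pool_names[a]; pb <- pool_names[b]
        if (is.null(res[[pa]]$dispersion) || is.null(res[[pb]]$dispersion))
          next
        comp[[paste(pa, pb, sep = "_vs_")]] <-
          two_sample_perm_test(res[[pa]]$dispersion, res[[pb]]$dispersion,
                               n_perm = n_perm,
                               rng_seed = rng_seed + 300L + a * 10L + b)
      }
  }
  res$dispersion_comparison <- comp

  write_outputs(out_dir,
    tables = if (!is.null(label_rows)) list(pair_labels = label_rows)
             else list(),
    json = list(pulse_summary = c(
      list(seed = rng_seed, n_null = n_null, n_null_rc = n_null_rc,
           dispersal_possible = dispersal_possible),
      frac_json,
      list(dispersion_comparison = comp))),
    manifest_lines = c(
      "assemblage pulse pipeline",
      sprintf("samples: %d  taxa: %d  pools: %s", ncol(cm), nrow(cm),
              paste(pool_names, collapse = ", ")),
      sprintf("n_null: %d  n_null_rc: %d  seed: %d  dispersal_possible: %s",
              n_null, n_null_rc, rng_seed, dispersal_possible)))
  res
}

#' Run a pipeline from a YAML configuration file
#'
#' The configuration names the mode (`gradient` or `pulse`), the input
#' paths (`tree`, `community`, `metadata`), the relevant columns, null
#' counts, seed and output directory; optional `min_occupancy` /
#' `min_mean_rel_abund` apply [filter_rare()] first.
#'
#' @param path Path to a YAML file.
#' @return The pipeline result list, invisibly.
#' @export
run_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  mode <- match.arg(cfg$mode, c("gradient", "pulse"))
  tree <- read_tree(cfg$tree)
  cm <- read_community(cfg$community)
  meta <- read_metadata(cfg$metadata)
  if (!is.null(cfg$min_occupancy) || !is.null(cfg$min_mean_rel_abund))
    cm <- filter_rare(cm,
                      min_occupancy = cfg$min_occupancy %||% 0,
                      min_mean_rel_abund = cfg$min_mean_rel_abund %||% 0)
  seed <- cfg$seed %||% 1L
  out <- if (mode == "gradient") {
    run_gradient_pipeline(tree, cm, meta,
                          axis_col = cfg$axis_col %||% "N_rate",
                          n_null = cfg$n_null %||% 1000,
                          breakpoint = cfg$breakpoint %||% 10.5,
                          rng_seed = seed, out_dir = cfg$out_dir)
  } else {
    run_pulse_pipeline(tree, cm, meta,
                       time_col = cfg$time_col %||% "time_h",
                       pool_col = cfg$pool_col %||% "group",
                       n_null = cfg$n_null %||% 1000,
                       n_null_rc = cfg$n_null_rc %||% 999,
                       n_perm = cfg$n_perm %||% 10000,
                       dispersal_possible =
                         isTRUE(cfg$dispersal_possible %||% FALSE),
                       rng_seed = seed, out_dir = cfg$out_dir)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
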