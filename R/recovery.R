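# Ground-truth recovery experiments: generate communities under a known
# assembly regime, run the full betaNTI + RC-bray + classification chain,
# and return the per-pair labels. These are the package's standard designs
# for validating inference against the generator's truth.

#' Run one assembly-process recovery experiment
#'
#' Simulates a species pool and communities under the requested regime,
#' computes betaNTI and RC-bray, and classifies the focal sample pairs.
#' The designs mirror how the corresponding processes are detected in
#' field studies:
#'
#' * `homogeneous_selection`: 12 focal samples assembled under one
#'   extreme selective environment (tight filter, founder mask 0.35,
#'   sparse depth) plus 12 "context" samples spanning the environmental
#'   axis. The null randomization runs over the whole data set — the
#'   species pool must contain environmental contrast for clustering of
#'   same-environment pairs to be detectable — and only focal-focal pairs
#'   are classified.
#' * `variable_selection`: 12 samples alternating between two distant
#'   environments; between-environment pairs are classified.
#' * `neutral`: 12 samples drawn from the pool with no filter; all pairs.
#' * `dispersal_limited`: as neutral but each sample colonized by a
#'   random half of the pool; all pairs.
#'
#' @param scenario One of the four regime names.
#' @param rng_seed Integer seed for the whole experiment.
#' @param n_null Null runs for betaNTI and RC-bray (default 499).
#' @param n_tips Species-pool size (default 600; structured tree).
#' @param n_individuals Sequencing depth per focal sample (default 200
#'   for `homogeneous_selection`, 300 otherwise).
#' @return List with `labels` (focal-pair labels), `fractions`
#'   (an `"assembly_fractions"` over those labels), `bnti`, `rc`, and
#'   `scenario`.
#' @export
assembly_recovery <- function(scenario = c("homogeneous_selection",
                                           "variable_selection", "neutral",
                                           "dispersal_limited"),
                              rng_seed, n_null = 499, n_tips = 600,
                              n_individuals = NULL) {
  scenario <- match.arg(scenario)
  seed <- as.integer(rng_seed)
  if (scenario == "homogeneous_selection") {
    if (is.null(n_individuals)) n_individuals <- 200
    tr <- simulate_structured_tree(max(2L, ceiling(n_tips / 5)), 5,
                                   rng_seed = seed)
    trt <- evolve_trait(tr, 1, 1, rng_seed = seed + 1L)
    cfg_f <- sim_config(n_tips = n_tips, scenario = scenario,
                        rng_seed = seed + 2L,
                        n_individuals = n_individuals)
    focal <- assemble_communities(tr, trt, cfg_f)$community
    ctx_env <- quantile(trt, seq(0.05, 0.95, length.out = 12),
                        names = FALSE)
    cfg_c <- sim_config(n_tips = n_tips, scenario = "variable_selection",
                        n_samples = 12, rng_seed = seed + 3L,
                        env_values = ctx_env, n_individuals = 500)
    ctx <- assemble_communities(tr, trt, cfg_c)$community
    colnames(ctx) <- sprintf("ctx%02d", seq_len(ncol(ctx)))
    cm <- cbind(focal, ctx)
    dmat <- patristic_distances(tr)
    bnti <- beta_nti(cm, dmat, n_null = n_null, rng_seed = seed + 50L)
    rc <- raup_crick_bray(cm, n_null = n_null, rng_seed = seed + 60L)
    cl <- classify_assembly(bnti, rc, dispersal_possible = TRUE)
    keep <- cl$pairs$sample_i %in% colnames(focal) &
      cl$pairs$sample_j %in% colnames(focal)
    labels <- cl$pairs$label[keep]
  } else {
    if (is.null(n_individuals)) n_individuals <- 300
    cfg <- sim_config(n_tips = n_tips, scenario = scenario,
                      rng_seed = seed, n_individuals = n_individuals)
    sim <- simulate_assembly(cfg)
    dmat <- patristic_distances(sim$tree)
    bnti <- beta_nti(sim$community, dmat, n_null = n_null,
                     rng_seed = seed + 50L)
    rc <- raup_crick_bray(sim$community, n_null = n_null,
                          rng_seed = seed + 60L)
    cl <- classify_assembly(bnti, rc, dispersal_possible = TRUE)
    labels <- cl$pairs$label
    if (scenario == "variable_selection") {
      g <- sim$metadata$group[match(cl$pairs$sample_i,
                                    sim$metadata$sample_id)] !=
        sim$metadata$group[match(cl$pairs$sample_j,
                                 sim$metadata$sample_id)]
      labels <- labels[g]
    }
  }
  list(labels = labels,
       fractions = process_fractions(labels, dispersal_possible = TRUE),
       bnti = bnti, rc = rc, scenario = scenario)
}

#' Pool recovery labels over replicate simulations
#'
#' Runs [assembly_recovery()] for several derived seeds and pools the
#' focal-pair labels, smoothing over tree-to-tree variability in guild
#' structure. The modal pooled label is the recovered process.
#'
#' @inheritParams assembly_recovery
#' @param n_replicates Number of replicate simulations (default 3).
#' @return List with pooled `labels`, `fractions`, and `modal` (the modal
#'   label).
#' @export
assembly_recovery_pooled <- function(scenario, rng_seed, n_replicates = 3,
                                     n_null = 499, n_tips = 600) {
  seeds <- as.integer(rng_seed) + 1000L * (seq_len(n_replicates) - 1L)
  labels <- unlist(lapply(seeds, function(s)
    assembly_recovery(scenario, s, n_null = n_null,
                      n_tips = n_tips)$labels))
  fr <- process_fractions(labels, dispersal_possible = TRUE)
  list(labels = labels, fractions = fr,
       modal = names(which.max(fr$fractions)))
}
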