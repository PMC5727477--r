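#' Configuration for a synthetic community simulation
#'
#' Bundles and validates the parameters of the generator. The generator
#' produces a species-pool tree (see `tree_model`), Brownian niche traits
#' with tunable phylogenetic signal, and communities assembled under a
#' known regime, so downstream inference can be checked against ground
#' truth.
#'
#' @param n_tips Number of taxa in the species pool (>= 2).
#' @param birth_rate Per-lineage birth rate of the pure-birth process(es).
#' @param trait_sigma2 Brownian rate of niche-trait evolution
#'   (trait units squared per unit branch length).
#' @param trait_lambda Pagel lambda transform applied to the trait
#'   covariance, in \[0, 1\] (1 = Brownian, 0 = no signal).
#' @param scenario One of `"homogeneous_selection"`, `"variable_selection"`,
#'   `"neutral"`, `"dispersal_limited"`.
#' @param env_values Optional numeric vector of per-sample environmental
#'   positions on the trait axis (length `n_samples`). When `NULL`,
#'   scenario-specific defaults are derived from the simulated traits.
#' @param tree_model Shape of the simulated species tree: `"structured"`
#'   (default; tight terminal clusters on a deep backbone, emulating the
#'   two-level shape of ribosomal gene trees), `"yule"` (pure birth), or
#'   `"coalescent"`.
#' @param filter_width Width (sd, trait units) of the Gaussian environmental
#'   filter; `Inf` disables filtering (neutral sampling). When `NULL`,
#'   scenario defaults are derived from the simulated traits (see
#'   [assemble_communities()]).
#' @param filter_floor Flat background sampling weight added to every
#'   taxon, expressed relative to the mean base abundance (default 5e-4):
#'   selection suppresses off-optimum taxa to a rare detectable background
#'   rather than eliminating them, emulating the persistent rare biosphere
#'   of amplicon surveys. Set to 0 for an absolute filter.
#' @param drift_sd Standard deviation of an independent per-sample,
#'   per-taxon log-normal abundance perturbation (default 0.5), emulating
#'   ecological drift and microscale heterogeneity between replicate
#'   communities. Set to 0 for deterministic weights.
#' @param colonization_prob Probability that a taxon is available to
#'   colonize a given sample (independent Bernoulli per taxon per sample):
#'   founder effects restricting local membership. `NULL` (default) uses
#'   scenario defaults: 0.35 under homogeneous selection, 0.5 under
#'   dispersal limitation, 1 (no restriction) otherwise.
#' @param n_individuals Individuals drawn per sample (multinomial total,
#'   default 300; sparse relative to the pool, as in amplicon surveys).
#' @param n_samples Number of samples (communities).
#' @param rng_seed Optional integer seed making the whole simulation
#'   reproducible.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_tips = 100, birth_rate = 1, trait_sigma2 = 1,
                       trait_lambda = 1,
                       scenario = c("homogeneous_selection",
                                    "variable_selection", "neutral",
                                    "dispersal_limited"),
                       env_values = NULL, tree_model = c("structured",
                                                         "yule",
                                                         "coalescent"),
                       filter_width = NULL, filter_floor = 5e-4,
                       drift_sd = 0.5, colonization_prob = NULL,
                       n_individuals = 300, n_samples = 12,
                       rng_seed = NULL) {
  scenario <- match.arg(scenario)
  tree_model <- match.arg(tree_model)
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  if (trait_sigma2 <= 0) stop("trait_sigma2 must be positive")
  if (trait_lambda < 0 || trait_lambda > 1)
    stop("trait_lambda must lie in [0, 1]")
  if (!is.null(filter_width) && !(filter_width > 0))
    stop("filter_width must be > 0 (use Inf for no filtering)")
  if (filter_floor < 0 || filter_floor >= 1)
    stop("filter_floor must lie in [0, 1)")
  if (drift_sd < 0) stop("drift_sd must be >= 0")
  if (!is.null(colonization_prob) &&
      (colonization_prob <= 0 || colonization_prob > 1))
    stop("colonization_prob must lie in (0, 1]")
  if (n_individuals < 1 || n_samples < 1)
    stop("n_individuals and n_samples must be positive")
  if (!is.null(env_values) && length(env_values) != n_samples)
    stop("env_values must have length n_samples")
  structure(list(n_tips = n_tips, birth_rate = birth_rate,
                 trait_sigma2 = trait_sigma2, trait_lambda = trait_lambda,
                 scenario = scenario, env_values = env_values,
                 tree_model = tree_model,
                 filter_width = filter_width, filter_floor = filter_floor,
                 drift_sd = drift_sd, colonization_prob = colonization_prob,
                 n_individuals = n_individuals, n_samples = n_samples,
                 rng_seed = rng_seed),
            class = "sim_config")
}

#' Simulate a pure-birth (Yule) species tree
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth_rate Per-lineage speciation rate.
#' @param rng_seed Optional integer seed.
#' @return An ultrametric rooted `"phylo"` tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, rng_seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  with_seed(rng_seed, {
    tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    validate_tree(tr)
    tr
  })
}

#' Simulate a two-level "structured" species tree
#'
#' Builds a pure-birth backbone of `n_clusters` lineages scaled to depth
#' `depth_ratio`, and replaces each backbone tip with an independent
#' pure-birth cluster of `cluster_size` tips scaled to depth 1. The result
#' emulates the two-level shape of ribosomal gene trees: tight terminal
#' clusters (congeneric sequence clusters) separated by long backbone
#' branches — the geometry under which terminal ("nearest taxon") metrics
#' carry most of their signal.
#'
#' @param n_clusters Number of terminal clusters (>= 2).
#' @param cluster_size Tips per cluster (>= 2).
#' @param depth_ratio Backbone depth relative to cluster depth
#'   (default 10).
#' @param birth_rate Per-lineage speciation rate of both levels.
#' @param rng_seed Optional integer seed.
#' @return An ultrametric rooted `"phylo"` tree with tips named
#'   `t<cluster>_<tip>`.
#' @export
simulate_structured_tree <- function(n_clusters, cluster_size = 5,
                                     depth_ratio = 10, birth_rate = 1,
                                     rng_seed = NULL) {
  if (n_clusters < 2 || cluster_size < 2)
    stop("n_clusters and cluster_size must be >= 2")
  with_seed(rng_seed, {
    bb <- ape::rphylo(n_clusters, birth = birth_rate, death = 0)
    bb$edge.length <- bb$edge.length * depth_ratio /
      max(ape::node.depth.edgelength(bb))
    anchors <- bb$tip.label
    for (i in seq_along(anchors)) {
      cl <- ape::rphylo(cluster_size, birth = birth_rate, death = 0)
      cl$edge.length <- cl$edge.length /
        max(ape::node.depth.edgelength(cl))
      cl$tip.label <- sprintf("t%d_%d", i, seq_len(cluster_size))
      bb <- ape::bind.tree(bb, cl,
                           where = which(bb$tip.label == anchors[i]))
    }
    validate_tree(bb)
    bb
  })
}

# Dispatch on the configured tree model. For "structured", n_tips is
# realized as ceiling(n_tips / 5) clusters of 5.
simulate_pool_tree <- function(config, rng_seed = NULL) {
  switch(config$tree_model,
    yule = simulate_tree(config$n_tips, config$birth_rate, rng_seed),
    coalescent = with_seed(rng_seed, {
      tr <- ape::rcoal(config$n_tips)
      validate_tree(tr)
      tr
    }),
    structured = simulate_structured_tree(
      max(2L, ceiling(config$n_tips / 5)), 5,
      birth_rate = config$birth_rate, rng_seed = rng_seed))
}

# lambda-transformed Brownian covariance: off-diagonals scaled by lambda,
# diagonal (tip depths) unchanged.
lambda_cov <- function(tree, sigma2 = 1, lambda = 1) {
  C <- ape::vcv(tree)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  sigma2 * Cl
}

#' Evolve a niche trait on a tree under lambda-scaled Brownian motion
#'
#' Draws one trait value per tip from a multivariate normal whose
#' covariance is the Brownian shared-path-length matrix with off-diagonal
#' entries scaled by `trait_lambda` (the transform is applied to the
#' covariance, which is equivalent to transforming the tree).
#'
#' @param tree A validated `"phylo"` tree.
#' @param trait_sigma2 Brownian rate.
#' @param trait_lambda Pagel lambda in \[0, 1\].
#' @param rng_seed Optional integer seed.
#' @return Named numeric vector of tip traits (root state 0).
#' @export
evolve_trait <- function(tree, trait_sigma2 = 1, trait_lambda = 1,
                         rng_seed = NULL) {
  validate_tree(tree)
  if (trait_lambda < 0 || trait_lambda > 1)
    stop("trait_lambda must lie in [0, 1]")
  V <- lambda_cov(tree, trait_sigma2, trait_lambda)
  L <- chol(V)
  with_seed(rng_seed, {
    z <- rnorm(nrow(V))
    setNames(as.numeric(crossprod(L, z)), rownames(V))
  })
}

# Scenario defaults for environments, filter width and colonization,
# derived from the simulated traits. Homogeneous selection targets the
# extreme end of the niche axis (where, under Brownian traits, the adapted
# guild is phylogenetically concentrated) with a width that is widened
# until the guild holds at least `min_guild` taxa so the selected set is
# neither a single tip nor the whole pool.
scenario_defaults <- function(traits, config, min_guild = 20) {
  ns <- config$n_samples
  sw <- config$filter_width
  env <- config$env_values
  colon <- config$colonization_prob
  switch(config$scenario,
    homogeneous_selection = {
      if (is.null(env)) env <- rep(quantile(traits, 0.995, names = FALSE),
                                   ns)
      if (is.null(sw)) {
        sw <- (max(traits) - quantile(traits, 0.99, names = FALSE)) / 2
        sw <- max(sw, 1e-8)
        guild <- function(w) sum(exp(-(traits - env[1L])^2 / (2 * w^2)) >
                                   0.05)
        while (guild(sw) < min(min_guild, length(traits))) sw <- sw * 1.3
      }
      if (is.null(colon)) colon <- 0.35
    },
    variable_selection = {
      if (is.null(sw)) sw <- 0.25 * sd(traits)
      if (is.null(env)) {
        lo <- quantile(traits, 0.1, names = FALSE)
        hi <- quantile(traits, 0.9, names = FALSE)
        env <- rep(c(lo, hi), length.out = ns)
      }
      if (is.null(colon)) colon <- 1
    },
    neutral = {
      if (is.null(sw)) sw <- Inf
      if (is.null(env)) env <- rep(NA_real_, ns)
      if (is.null(colon)) colon <- 1
    },
    dispersal_limited = {
      if (is.null(sw)) sw <- Inf
      if (is.null(env)) env <- rep(NA_real_, ns)
      if (is.null(colon)) colon <- 0.5
    })
  list(env = env, filter_width = sw, colonization = colon)
}

# Gaussian filter factor for one sample (1 everywhere when width = Inf).
filter_factor <- function(traits, env, width) {
  if (!is.finite(width) || is.na(env)) rep(1, length(traits))
  else exp(-(traits - env)^2 / (2 * width^2))
}

# Sampling weights for one sample: filtered base abundances, founder
# (colonization) mask, log-normal drift, plus a flat rare-biosphere floor.
sample_weights <- function(base, traits, env, width, floor, drift_sd,
                           colonization) {
  w <- base * filter_factor(traits, env, width)
  if (colonization < 1) {
    repeat {
      mask <- rbinom(length(w), 1L, colonization)
      if (any(w * mask > 0) || floor > 0) break
    }
    w <- w * mask
  }
  if (drift_sd > 0) w <- w * exp(rnorm(length(w), 0, drift_sd))
  w <- w + floor * mean(base)
  if (all(w == 0))
    stop("all sampling weights are zero; the environment lies beyond ",
         "every niche - increase filter_width or filter_floor")
  w
}

#' Assemble communities under a known ecological regime
#'
#' For each sample with environment E, sampling weights are
#' `base * exp(-(trait - E)^2 / (2 filter_width^2)) * mask * drift
#' + filter_floor * mean(base)` — a Gaussian environmental filter on the
#' niche trait, a Bernoulli founder mask (see `colonization_prob` in
#' [sim_config()]), independent per-sample log-normal drift, and a flat
#' rare-biosphere floor — and `n_individuals` individuals are drawn
#' multinomially. Scenario defaults: `homogeneous_selection` (one shared
#' E at the extreme of the niche axis, filter just wide enough to admit
#' an adapted guild of ~20+ taxa, founder mask 0.35), `variable_selection`
#' (E alternates between two distant positions, width 0.25 sd),
#' `neutral` (no filter), `dispersal_limited` (no filter, founder mask
#' 0.5). Base abundances are log-normal (meanlog 0, sdlog 1).
#'
#' @param tree Species-pool tree.
#' @param traits Named per-tip niche traits (see [evolve_trait()]).
#' @param config A [sim_config()].
#' @return List with `community` (taxa x samples integer matrix),
#'   `metadata` (sample_id, group, env), and `truth` (scenario, traits,
#'   base abundances, filter width, colonization probability).
#' @export
assemble_communities <- function(tree, traits, config) {
  validate_tree(tree)
  stopifnot(inherits(config, "sim_config"))
  if (!setequal(names(traits), tree$tip.label))
    stop("traits must be named by the tree's tip labels")
  traits <- traits[tree$tip.label]
  with_seed(config$rng_seed, {
    n <- length(traits)
    base <- setNames(rlnorm(n, 0, 1), names(traits))
    sc <- scenario_defaults(traits, config)
    ns <- config$n_samples
    cm <- matrix(0L, n, ns,
                 dimnames = list(names(traits),
                                 sprintf("s%02d", seq_len(ns))))
    for (s in seq_len(ns)) {
      w <- sample_weights(base, traits, sc$env[s], sc$filter_width,
                          config$filter_floor, config$drift_sd,
                          sc$colonization)
      cm[, s] <- rmultinom(1L, config$n_individuals, w)
    }
    group <- if (config$scenario == "variable_selection") {
      blocks <- as.integer(factor(sc$env, levels = unique(sc$env)))
      sprintf("env_%d", blocks)
    } else rep(config$scenario, ns)
    meta <- data.frame(sample_id = colnames(cm), group = group,
                       env = sc$env, stringsAsFactors = FALSE)
    list(community = cm, metadata = meta,
         truth = list(scenario = config$scenario, traits = traits,
                      base_abundance = base,
                      filter_width = sc$filter_width, env = sc$env,
                      colonization = sc$colonization))
  })
}

#' One-call synthetic data set: tree, traits, communities
#'
#' @param config A [sim_config()].
#' @return List with `tree`, `traits`, `community`, `metadata`, `truth`.
#' @export
simulate_assembly <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$rng_seed
  tree <- simulate_pool_tree(config,
                             rng_seed = if (is.null(seed)) NULL else seed)
  traits <- evolve_trait(tree, config$trait_sigma2, config$trait_lambda,
                         rng_seed = if (is.null(seed)) NULL else seed + 1L)
  cfg2 <- config
  cfg2$rng_seed <- if (is.null(seed)) NULL else seed + 2L
  out <- assemble_communities(tree, traits, cfg2)
  c(list(tree = tree, traits = traits), out)
}

#' Linearly rescale trait values onto a target axis range
#'
#' Convenience for placing simulated niche optima onto a concrete axis
#' (e.g. log-hours of a pulse experiment).
#'
#' @param traits Numeric vector.
#' @param lower,upper Target range.
#' @return Rescaled vector with names preserved.
#' @export
rescale_traits <- function(traits, lower, upper) {
  r <- range(traits)
  if (diff(r) == 0) return(setNames(rep((lower + upper) / 2,
                                        length(traits)), names(traits)))
  setNames(lower + (traits - r[1]) / diff(r) * (upper - lower),
           names(traits))
}

#' Simulate a pulse time series of activity profiles
#'
#' One community per time point (and replicate) is drawn with Gaussian
#' activity filters on the natural-log time axis; each taxon's optimum on
#' ln(time) is its ground-truth temporal niche. Time points default to the
#' rewetting sampling scheme 0.5 h to 144 h.
#'
#' @param tree Species-pool tree.
#' @param optima Named per-tip temporal optima on the ln-hours scale
#'   (e.g. [evolve_trait()] output passed through [rescale_traits()]).
#' @param config A [sim_config()]; `filter_width` is interpreted on the
#'   ln-hours axis (default 0.5 x sd(optima) when `NULL`).
#' @param times_h Strictly positive sampling times in hours.
#' @param replicates Communities per time point.
#' @return List with `community`, `metadata` (sample_id, group, time_h,
#'   ln_time), and `truth` (optima, base abundances, filter width).
#' @export
simulate_pulse_series <- function(tree, optima, config,
                                  times_h = c(0.5, 2, 8, 24, 48, 72, 96, 144),
                                  replicates = 1) {
  validate_tree(tree)
  stopifnot(inherits(config, "sim_config"))
  if (any(times_h <= 0)) stop("time points must be strictly positive")
  if (!setequal(names(optima), tree$tip.label))
    stop("optima must be named by the tree's tip labels")
  optima <- optima[tree$tip.label]
  with_seed(config$rng_seed, {
    n <- length(optima)
    base <- setNames(rlnorm(n, 0, 1), names(optima))
    sw <- config$filter_width
    if (is.null(sw)) sw <- 0.5 * sd(optima)
    ids <- as.vector(outer(seq_along(times_h), seq_len(replicates),
                           function(i, r) sprintf("T%02d_r%d", i, r)))
    tt <- rep(times_h, times = replicates)
    lt <- log(tt)
    cm <- matrix(0L, n, length(ids),
                 dimnames = list(names(optima), ids))
    for (k in seq_along(ids)) {
      w <- sample_weights(base, optima, lt[k], sw, config$filter_floor,
                          config$drift_sd, colonization = 1)
      cm[, k] <- rmultinom(1L, config$n_individuals, w)
    }
    meta <- data.frame(sample_id = ids,
                       group = rep("pulse", length(ids)),
                       time_h = tt, ln_time = lt, stringsAsFactors = FALSE)
    list(community = cm, metadata = meta,
         truth = list(optima = optima, base_abundance = base,
                      filter_width = sw))
  })
}
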