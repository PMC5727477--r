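---
title: "Inferring community assembly processes with phylogenetic null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes with phylogenetic null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference problem

Microbial communities are assembled by a mixture of deterministic
(selection by the abiotic and biotic environment) and stochastic
(dispersal, ecological drift) processes. Composition alone cannot
separate them: very different process mixtures can produce similar
dissimilarity values. The framework implemented here leverages the
phylogeny: when ecological niches carry phylogenetic signal — close
relatives have similar niches — the *phylogenetic* turnover between two
communities is informative about selection, and its deviation from a
null model yields a process classification for every pair of
communities.

`assemblage` implements that framework end to end:

1. **Phylogenetic signal screening.** Abundance-weighted niche optima
   per taxon (`niche_optima()`), Pagel's lambda by maximum likelihood
   with a likelihood-ratio test (`pagels_lambda()`), and a Mantel
   correlogram over standardized patristic distance classes
   (`mantel_correlogram()`). Signal at short phylogenetic distances is
   the precondition for all downstream inference.
2. **Turnover metrics.** Abundance-weighted between-community mean
   nearest taxon distance (`beta_mntd()`, a "terminal" metric) and mean
   pairwise distance (`beta_mpd()`, a "basal" metric), Faith's PD and
   its standardized effect size (`faith_pd()`, `ses_pd()`), and
   Bray-Curtis dissimilarity (`bray_curtis()`).
3. **Null models.** Tip-label shuffling yields the standardized effect
   sizes betaNTI (`beta_nti()`) and betaNRI (`beta_nri()`); a
   Raup-Crick null preserving taxon occurrence frequencies and sample
   richness yields RC-bray (`raup_crick_bray()`).
4. **Classification.** Per-pair labels and aggregate process fractions
   (`classify_pairs()`, `process_fractions()`).
5. **Study designs.** `run_gradient_pipeline()` (spatial turnover along
   a press gradient) and `run_pulse_pipeline()` (temporal turnover of
   closed microcosms after a pulse disturbance).
6. **Synthetic data with known truth.** `simulate_assembly()` and
   friends generate trees, niche traits and communities under known
   regimes, so every stage can be validated against ground truth
   (`assembly_recovery()`).

# The null models

## Tip shuffling: betaNTI and betaNRI

For a pair of samples $j,k$ the observed metric is the
abundance-weighted mean nearest taxon distance

$$\beta\mathrm{MNTD}_{jk} = \tfrac12\Big(\sum_{i\in j} f_{ij}
\min_{i'\in k} d_{ii'} + \sum_{i'\in k} f_{i'k} \min_{i\in j}
d_{i'i}\Big),$$

with $f$ the within-sample relative abundances and $d$ the patristic
distance; $\beta\mathrm{MPD}$ replaces the minima by the full
abundance-weighted double sum. The null randomizes the *phylogenetic
identity* of the taxa: one permutation of the distance-matrix rows and
columns per null run, shared by all sample pairs (a whole-data-set
randomization). This fixes observed alpha- and beta-diversity exactly
and asks only whether the taxa involved are more (or less) closely
related than chance. The standardized deviation

$$\beta\mathrm{NTI}_{jk} = \frac{\beta\mathrm{MNTD}^{obs}_{jk} -
\overline{\beta\mathrm{MNTD}^{null}_{jk}}}
{\mathrm{sd}\,\beta\mathrm{MNTD}^{null}_{jk}}$$

is read against $\pm 2$, the conventional rounding of the two-sided 5%
normal critical value $\pm 1.96$ (`deviation_threshold()`): values
below $-2$ indicate homogeneous selection (less phylogenetic turnover
than expected), above $+2$ variable selection. Pairs whose null
standard deviation is numerically zero (below `1e-10`; e.g. two
identical communities, where every taxon matches itself at distance 0
under any shuffle) are flagged undefined rather than propagated as
infinities, and are reported separately everywhere.

The *species pool* is explicit: a pool is a set of samples whose union
of observed taxa defines the shuffle universe (the `pool` argument).
Pools matter — see "Known limitations" below.

## Raup-Crick on Bray-Curtis: RC-bray

Each sample is reassembled under a null that preserves what drift alone
would preserve: taxa are drawn without replacement with probability
proportional to their pool occurrence frequency until the observed
richness is reached, then the observed number of individuals is
distributed over the drawn taxa with probability proportional to pool
relative abundance. Every drawn taxon receives at least one individual,
so sample richness is preserved exactly. With $n_<$ and $n_=$ the null
draws below/equal to the observed Bray-Curtis,

$$RC_{bray} = 2\,\frac{n_< + n_=/2}{n_{null}} - 1 \in [-1, 1].$$

$RC_{bray} > 0.95$ marks more compositional turnover than the drift
expectation, $RC_{bray} < -0.95$ less. One reassembly of every sample
per null run is shared across pairs; the marginal null distribution per
pair is identical to independent per-pair reassembly.

## Classification

With dispersal possible (open systems): betaNTI $< -2$ homogeneous
selection; $> +2$ variable selection; otherwise RC-bray $> 0.95$
dispersal limitation coupled with drift, $< -0.95$ homogenizing
dispersal, and $|RC| \le 0.95$ undominated. In closed systems
(`dispersal_possible = FALSE`, e.g. sealed microcosms) the
low-turnover branch instead estimates *weak homogeneous selection* —
selection too weak to leave a phylogenetic imprint but strong enough to
constrain composition. All inequalities are strict; a value landing
exactly on a threshold (measure zero for continuous statistics, but
possible in degenerate data) is assigned "undominated" and reported.
Fractions are computed over defined pairs and always reported for all
seven categories (including "undefined" counts), so the accounting
sums to one by construction.

# Phylogenetic signal procedures

`pagels_lambda()` fits, by maximum likelihood, the multivariate normal
trait model whose covariance is the Brownian shared-path-length matrix
with off-diagonal entries scaled by $\lambda \in [0,1]$; $\sigma^2$ and
the root state are profiled analytically (GLS), and $\lambda$ is
optimized to a tolerance of `1e-8` with the endpoints checked
explicitly. Because $\lambda = 0$ lies on the boundary of the parameter
space, the likelihood-ratio p-value uses the boundary-aware mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (i.e. the $\chi^2_1$ tail halved)
— slightly conservative relative to a plain $\chi^2_1$ test, which is
the safer reading when the test is a gatekeeper for downstream
inference.

`mantel_correlogram()` standardizes patristic distances by their
maximum and partitions them into classes of width 0.02 (half-open
intervals, last class closed). Per class, the Mantel correlation
between the niche distance matrix and the binary class-membership
matrix is computed and sign-flipped so that positive $r$ means
"more similar niches than average within this distance class" — the
autocorrelogram convention of vegan's `mantel.correlog`, with which the
statistic agrees to machine precision (tested). P-values come from
permuting taxon labels (two-tailed, $(\text{count}+1)/(n_{perm}+1)$)
and are corrected progressively (Holm over the classes up to and
including each class, in increasing distance order). Classes with
fewer than `min_pairs = 10` pairs are reported but not tested.

# Group statistics

* `mantel_test()`: Pearson correlation of the upper triangles with
  joint row/column permutations of the first matrix. The default tail
  is "greater", the convention under which a negative observed
  correlation yields p near 1. Undefined (NA) pairs are dropped
  pairwise, in the observed and each permuted correlation alike.
* `mean_deviation_test()`: Monte Carlo test of a group's mean deviation
  against zero by independent random sign flips — valid when each
  deviation's null distribution is symmetric about zero, which is the
  designed behaviour of a standardized effect size.
* `permdisp()`: principal-coordinates embedding, distance to own-group
  centroid, and a permutation F-test of dispersion homogeneity (backed
  by `vegan::betadisper` with `type = "centroid"`, which reproduces
  direct Euclidean geometry exactly on Euclidean inputs — tested).
  Signed deviation matrices are first shifted by the absolute minimum
  of the off-diagonal entries; this preserves the ranking of
  dissimilarities but is only one possible convention for signed
  inputs, so dispersion results on shifted matrices should be read as
  ordinal.
* `segmented_fit()`: two independent ordinary least-squares fits with a
  *user-fixed* breakpoint, the boundary sample included in both
  segments (matching printed range conventions such as "0–10.5 and
  10.5–28"); case-resampling percentile bootstrap (1000 draws) gives
  95% intervals and bands. No breakpoint search is performed — the
  breakpoint is a design choice, not an estimate.
* Time axes and pairwise gradient differences are natural-log
  transformed (`ln_abs_diff()`); zero differences (replicate pairs)
  are replaced by half the smallest positive difference with a message,
  since the data give no information below that resolution.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which the whole pipeline is validated.

**Species pool.** `simulate_structured_tree()` builds the default pool
tree: pure-birth clusters of 5 tips (depth 1) on a pure-birth backbone
(depth 10). This two-level geometry — many tight terminal clusters
separated by long interior branches — is the shape of ribosomal gene
trees, where OTUs fall into dense congeneric clusters below deep trunk
splits, and it is the geometry under which "terminal" metrics like
betaMNTD carry signal. Plain pure-birth (`"yule"`) and coalescent
(`"coalescent"`) shapes are available; on pure-birth trees even the
most extreme Brownian-trait sets are substantially polyphyletic
(nearest-neighbour distances of top-decile trait sets are ~19% of the
tree-wide mean pairwise distance, versus ~1% on coalescent trees), so
clade-level niche conservatism — the biological premise of the
framework — is poorly emulated by a single-level pure-birth pool.

**Niche traits.** `evolve_trait()` draws one trait per tip from the
lambda-scaled Brownian covariance (the transform is applied to the
covariance matrix, which is equivalent to transforming the tree and
simpler to verify against the analytic matrix).

**Communities.** For each sample with environment $E$ the sampling
weights are

$$w_i = b_i \exp\!\Big(-\frac{(z_i - E)^2}{2\sigma_w^2}\Big)
\cdot m_i \cdot e^{\epsilon_i} + \phi\,\bar b,$$

with $b_i$ log-normal(0, 1) base abundances, $z_i$ the niche trait,
$\sigma_w$ the filter width, $m_i \sim$ Bernoulli(colonization) founder
masks, $\epsilon_i \sim N(0, \mathrm{drift\_sd}^2)$ per-sample
log-normal drift, and $\phi$ a flat rare-biosphere floor relative to
the mean base abundance. `n_individuals` individuals are then drawn
multinomially. Each ingredient emulates a documented feature of real
amplicon data sets, and each is individually switchable:

* *Drift* (`drift_sd = 0.5`): replicate communities differ in which
  taxa dominate. Without it, i.i.d. multinomial replicates are nearly
  identical — and betaNTI deviations are carried **only** by non-shared
  taxa (a taxon present in both samples matches itself at distance zero
  under every tip shuffle), so a generator without between-replicate
  turnover produces no deviations at all, under any regime.
* *Founder masks* (`colonization_prob`; 0.35 under homogeneous
  selection, 0.5 under dispersal limitation, 1 otherwise): priority
  effects restrict which pool members reach each community. Under
  selection this creates turnover *within* the adapted clade — the
  signature that betaNTI reads as homogeneous selection.
* *Rare-biosphere floor* (`filter_floor = 5e-4`): selection suppresses
  off-optimum taxa to a rare, detectable background rather than
  eliminating them. This keeps the realized species pool broader than
  the selected guild.
* *Sparse depth* (`n_individuals = 300` against pools of hundreds of
  taxa): per-sample richness well below pool size, as in rarefied
  amplicon tables. Saturated samples (richness near pool size) make
  the null's nearest-taxon distances collapse and cap all deviations
  near zero.

**Scenario defaults.** Homogeneous selection targets the extreme end of
the niche axis (E at the 99.5th trait percentile) with a width widened
just until the adapted guild holds at least 20 taxa: under Brownian
traits the *extreme* of the niche axis is where trait and phylogeny
align, whereas taxa matching an interior niche value are drawn from
many unrelated lineages (selection for an interior optimum is
phylogenetically diffuse and correctly yields no betaNTI signal).
Variable selection alternates samples between the 10th and 90th trait
percentiles with width $0.25\,\mathrm{sd}$. The temporal generator
(`simulate_pulse_series()`) uses Gaussian activity filters on
ln(time in hours) with default sampling times 0.5 h–144 h.

**What the generator does not emulate.** Sequencing error, chimeras,
compositional (relative-abundance) artefacts, spatial structure within
samples, and true birth-death extinction dynamics. Passing recovery
tests therefore show that the inference chain is mathematically sound
under its own assumptions — not that those assumptions hold in any
particular real data set.

# Validation designs and problem sizes

The test suite and the acceptance script validate the chain at sizes
chosen to give stable Monte-Carlo estimates:

* **Oracle equivalence.** betaMNTD, betaMPD, Faith's PD, patristic
  distances and Bray-Curtis against naive brute-force implementations
  on 50 random instances (up to 20 taxa, 8 samples), within `1e-10`;
  plus cross-checks against picante and vegan.
* **Null calibration.** Neutral communities (100 tips, 12 samples,
  999 nulls): about 95% of pairs fall within betaNTI, betaNRI of
  $\pm 2$. RC-bray evaluated on 210 pairs generated by its own null
  (shared pool statistics) is centred on zero.
* **Process recovery** (600-tip pools, 499 nulls). Each scenario's
  generating process is the modal inferred label. Homogeneous
  selection is evaluated the way it is detected in field studies: 12
  focal same-environment samples *plus* 12 context samples spanning
  the environmental axis, with the null randomized over the whole
  data set and only focal pairs classified, pooled over three
  replicate simulations. The context is not optional — see below.
* **Signal recovery.** Pagel's lambda at truth 0 and 1 (20 replicates
  each, 100 tips); correlogram positive and significant in the
  shortest distance classes with the short-class mean exceeding the
  deep-class mean; class-level false-positive rate ~5% on shuffled
  traits (200 runs).
* **Test calibration.** Sign-flip mean test and Mantel test hold 5%
  type-I error within Monte-Carlo tolerance (200 null runs each);
  PERMDISP detects a threefold dispersion difference at n = 20 per
  group.

# Known limitations

* **A union-scoped null cannot see uniform selection.** The shuffle
  universe is the union of taxa observed in the pool samples. If
  *every* sample experiences the same selective environment, that
  union *is* the selected guild (plus rare background), and shuffling
  within it reproduces the observed clustering: betaNTI is
  structurally near zero no matter how strong selection is. Detecting
  homogeneous selection requires environmental contrast somewhere in
  the species pool — which is exactly how the classical field designs
  work (within-level pairs evaluated under a whole-gradient
  randomization). Users analysing single-condition data sets should
  interpret near-zero betaNTI accordingly.
* **betaNTI magnitude is bounded by sample richness.** The deviation is
  a mean over the non-shared taxa of a pair; with few non-shared taxa
  (low richness, or high overlap) the null standard deviation is large
  and $|\beta\mathrm{NTI}|$ rarely exceeds ~2 even under strong
  structure. Saturated samples (richness near the pool size) bound it
  from the other side.
* **RC-bray compares against one specific drift model.** Communities
  generated by a different stochastic process (e.g. i.i.d. multinomial
  sampling at great depth) can sit far into the tails of the RC null
  without any deterministic process acting; RC values should be read
  as "relative to the occurrence/richness-preserving null", not as
  absolute evidence.
* **Signed-matrix PERMDISP** uses a shift convention (above); absolute
  dispersion values depend on that convention even though group
  rankings typically do not.
* **Degenerate inputs** (identical replicate communities, star-like
  trees, constant niche values, all-equal distances) are flagged and
  excluded rather than silently propagated; every such rule is
  exercised in the test suite.

# Reproducibility

Every stochastic function takes an `rng_seed`; pipeline stages derive
per-stage seeds from one master seed, so a pipeline rerun with the same
inputs and seed is identical artifact-for-artifact. Seeded calls
restore the caller's RNG state on exit.
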