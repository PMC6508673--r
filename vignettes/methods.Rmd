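---
title: "Methods: models, priors, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, priors, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in
`ghostbirds`, the numerical choices behind them, and the rationale (and
limits) of the synthetic-data generator. It is the reference for every
convention the package fixes; function documentation states *what* each
function returns, this document states *why*.

## 1. Scientific setting

Rising sea level pushes saltwater into low-lying coastal forests, killing
stands and leaving "ghost forests" of standing dead trees with strongly
reduced midstory (4.5–10 m) and canopy (20–30 m) vegetation density.
The pipeline asks three questions:

1. Can ghost forest be recognized from LiDAR-style vegetation-structure
   metrics alone?
2. How do individual bird species — observed imperfectly on repeat point
   counts — respond to the vegetation structure that saltwater exposure
   changes?
3. How many hectares of each species' habitat were lost or gained over a
   decade, and where?

Each question maps to a module: `stepwise_select()` and its companions
(classification), `sample_posterior()` and its summaries (community
occupancy model), `richness_posterior()` / `group_pif_scores()`
(community metrics), and `stratified_change()` (habitat accounting).
`simulate_landscape()` and the other generators stand in for field and
LiDAR data so the full pipeline runs and is testable end to end.

## 2. The hierarchical multi-species occupancy model

For species $k$ at site $i$ with sampling occasion $j$:

$$z_{ik} \sim \mathrm{Bernoulli}(\psi_{ik}), \qquad
  y_{ijk} \mid z_{ik} \sim \mathrm{Bernoulli}(z_{ik}\, p_{ijk})$$

$$\operatorname{logit}(p_{ijk}) = \alpha_{0k} + \alpha_{Ak} R^A_i
  + \alpha_{Bk} R^B_i$$

$$\operatorname{logit}(\psi_{ik}) = \beta_{0k} + \beta_{1k}\,x^{mid}_i
  + \beta_{2k}\,x^{can}_i + \beta_{3k}\,\mathrm{burned}_i$$

where $x^{mid}$ and $x^{can}$ are midstory and canopy density
standardized over the survey sites (sample sd, $n-1$ denominator), and
$R^A, R^B$ are dummy contrasts for two observer routes against an
off-route reference. The route covariate is written as a single term in
many occupancy applications; with three observer groups, two
species-specific contrasts are the faithful dummy coding, so each species
has six coefficients plus a detection intercept.

Species coefficients are random effects: each family (detection
intercept, each route contrast, occupancy intercept, the three occupancy
effects) has a community mean $\mu$ and sd $\sigma$, with

* $\mu \sim \mathrm{Normal}(0, \mathrm{var}\ 1000)$ — a vague prior on
  the logit scale;
* $\sigma \sim \mathrm{Half\text{-}Normal}(\mathrm{scale}\ 2.25)$.

The half-normal on the sd scale is a package decision (configurable via
`sigma_scale`): vague inverse-gamma variance priors behave badly when a
family's variance is near zero, while a half-normal with scale 2.25 keeps
about 95% of its mass below 4.4 — already an enormous between-species
spread on the logit scale — yet has positive density at 0.

### 2.1 Sampler

`sample_posterior()` runs a Metropolis-within-Gibbs sampler written for
this model (C++ core):

* **Latent states.** $z_{ik}$ is 1 with certainty where the species was
  detected; otherwise it is drawn from its closed-form full conditional
  $\psi q / (\psi q + 1 - \psi)$ with $q = \prod_j (1 - p_{ijk})$
  (`full_conditional_z()` is the exported scalar version).
* **Species coefficients.** Per-parameter random-walk Metropolis on the
  z-augmented Bernoulli likelihood. Proposal scales adapt in batches of
  50 during burn-in toward the 23–44% acceptance window and are frozen
  afterwards, so the post-burn-in chain is a fixed Markov kernel.
* **Community means.** Conjugate normal draws given the species
  coefficients.
* **Community sds.** Log-scale random-walk Metropolis under the
  half-normal prior.
* **Interweaving moves.** Hierarchical location and scale parameters mix
  poorly under purely centred updates (the "funnel": when $\sigma$ is
  small the species coefficients pin $\mu$ and $\sigma$ in place). Two
  ancillarity–sufficiency interweaving moves fix this: a *shift* move
  proposes translating a community mean and all its species coefficients
  jointly (species deviations — the non-centred coordinates — are
  unchanged, so only the data likelihood and the $\mu$ hyperprior enter
  the ratio), and a *rescale* move multiplies $\sigma$ and all species
  deviations by a common factor $c = e^d$ (the non-centred random-effect
  densities cancel against the Jacobian $c^{K+1}$ up to a residual
  $\log c$, leaving likelihood ratio + half-normal prior ratio +
  $\log c$). Both moves run every iteration; their likelihood cost is
  contained by evaluating $\log\sigma(\eta)$ and $\log(1-\sigma(\eta))$
  from a single exponential, buffering proposed values so acceptance
  copies rather than recomputes, and skipping sites whose covariate value
  is exactly zero (route indicators, burned dummy), where the
  likelihood-ratio contribution is exactly zero. Without the rescale
  move, the sd of the burned effect (a weakly identified binary
  covariate) reached $\hat R = 1.26$ at reduced chain lengths; with it,
  $\hat R$ stays near 1.03.

Because detection covariates are site-level, the per-site detection
counts are sufficient statistics; the sampler works from
$\sum_j y_{ijk}$ and the per-site occasion count rather than the full
array, and caches the log detection/occupancy probabilities so each
Metropolis step only evaluates what the proposal changes.

`n_iter` is the **total** chain length including burn-in: retained draws
per chain $= (n_\mathrm{iter} - n_\mathrm{burn}) / \mathrm{thin}$.
Defaults are 3 chains × 20 000 iterations, 5 000 burn-in, thin 5. Chain
$c$ is seeded with `seed + c - 1`, so runs are reproducible per
(seed, chain).

### 2.2 Numerical conventions

* **Marginal likelihood** (`loglik_marginal()`): the latent state is
  summed out per site × species in log space (`log-sum-exp`); tests
  verify exact agreement (1e-10) with brute-force enumeration over all
  $2^{MK}$ configurations on small instances.
* **Intervals**: central 95%, equal-tailed, type-7 quantiles of the
  pooled post-burn-in thinned draws. Type 7 is R's default interpolation
  rule; e.g. draws $1..100$ give $(3.475,\ 97.525)$.
* **$\hat R$** (`gelman_rubin()`): $\sqrt{((n-1)/n \cdot W + B/n)/W}$
  with $W$ the mean within-chain variance and $B$ the between-chain
  variance of chain means (times $n$); parameters with zero within-chain
  variance are reported `NA`. This is the classic formula without the
  sampling-variability degrees-of-freedom correction; tests cross-check
  against `coda::gelman.diag()`.
* **Support classification** (`classify_support()`): an effect is
  *strong* when its 95% interval excludes zero; an endpoint exactly at
  zero counts as inclusion (weak). Direction is the sign of the
  posterior mean.
* **Standardization**: sample sd ($n-1$); the constants travel with the
  `site_design` and are reused unchanged for raster prediction, because
  the fitted coefficients are only valid on the scale they were fit on.

## 3. Ghost-forest classification

`stepwise_select()` implements correlation-constrained stepwise AIC
selection over the seven vegetation metrics:

1. Step 1 keeps the single-metric logistic model with the lowest AIC.
2. Later steps consider only metrics whose absolute Pearson correlation
   with **every** already-selected metric is below 0.5. Applying the
   gate to all previous selections (not just the first) is the
   conservative generalization of a gate described relative to step 1.
3. The best candidate is accepted only if it **strictly** lowers AIC;
   otherwise the more parsimonious model is kept and selection stops.
   No ΔAIC < 2 tolerance is applied: within a step the strict minimum
   decides, across steps parsimony decides.

Perfect separation — common on synthetic draws with a hard structural
break — is detected and handled with a tiny ridge penalty (1e-6) plus a
warning, so the pipeline never produces infinite coefficients.
`exhaustive_select()` enumerates every pairwise-correlation-feasible
subset with ordinary `glm()` fits; it exists purely as an independent
oracle and agreement is part of the test suite.

Validation follows a class-stratified 60/40 train/holdout split
(`split_train_validation()`; base-R sampling, seed-reproducible) and
reports sensitivity and specificity at a 0.5 probability threshold
(`evaluate_sensitivity_specificity()`).

## 4. Community metrics

Site richness is the draw-wise sum of latent states
$S_i = \sum_k z_{ik}$, summarized after the fact
(`richness_posterior()`), which preserves the full posterior of a
nonlinear functional instead of plugging in posterior means. Richness
regressions (`regress_richness()`) use the posterior **median** per site
as the response in per-metric OLS fits. Conservation scoring
(`group_pif_scores()`) averages priority scores over species with at
least one strongly supported negative density effect ("ghost-associated")
and over species with at least one strongly supported positive effect;
the groups may overlap and an empty group is `NA`, not 0.

## 5. Habitat-change accounting

`stratified_change()` runs, per species:

1. Aggregate both epochs' rasters from the 12-m metric grid to the 48-m
   analysis grid (factor 4): block means for densities, block majority
   for binary flags. A 48-m cell is 0.2304 ha.
2. Predict occupancy per cell from posterior-mean coefficients, with
   densities standardized by the survey-site constants and the burned
   flag held at its **observed** status in both epochs, so the change
   isolates vegetation-structure change rather than re-litigating the
   fire.
3. Difference (late − early), threshold at ±0.3 with **strict**
   inequalities — a cell at exactly −0.30 is *no change* — and sum
   loss/gain cells × cell area within strata: whole area, burned
   perimeter, unburned low-lying forest, and (optionally) the
   ghost-transition blocks themselves.

Posterior-mean coefficients are the default (matching map-style outputs);
`predict_occupancy()` accepts any coefficient row, so full posterior
propagation is a loop over draws if wanted.

## 6. The synthetic generator: realism and limits

`simulate_landscape()` builds seven metric surfaces from smoothed
Gaussian noise driven by shared latent fields ("stand maturity", shrub
and subcanopy structure), so the metrics are spatially autocorrelated
and mutually collinear, as real LiDAR metrics are. Default fractions:
15% burned, 35% low-lying, 10% ghost transitions (confined to unburned
low-lying cells). Deliberate design choices, with their reasons:

* **Clumped transitions.** Ghost cells are Bernoulli draws whose
  per-cell probability follows a smoothed exposure field, scaled so the
  expected count is `ghost_fraction * ncell`. Independent uniform draws
  would scatter single 12-m cells that dilute to ~10% of any 48-m block,
  making a |Δψ| > 0.3 crossing impossible for any species — real ghost
  forests die in shoreline patches, and the analysis scale demands that
  structure.
* **Jittered severity.** The midstory/canopy reduction factor (default
  0.3) gets per-cell lognormal jitter (clamped to [0.02, 0.9]). A single
  fixed factor makes ghost and intact stands perfectly separable, which
  degenerates the AIC comparisons and drives sensitivity/specificity to
  exactly 1 — structurally uninformative for testing a classifier.
* **Biomass labels.** The training response is the sign of a structural
  biomass proxy (layer densities × layer mid-heights, 7.25/15/25 m).
  Burned cells also lose biomass — realistically — so label agreement
  with the ghost mask is evaluated on unburned cells; the training
  sampler (`sample_metric_table()`) draws only from the unburned
  low-lying stratum for the same reason field training data would.
* **Metric-table spacing.** Training points default to 100-m minimum
  spacing, not the 400-m survey-site spacing: the generator's spatial
  correlation length (smoothing sigma 6 cells ≈ 72 m) is much shorter
  than a real landscape's, so 100 m already yields effectively
  independent points while leaving room for 248 of them in the low-lying
  stratum of a moderate grid.
* **Detection design.** Route sites get 3 occasions; off-route sites
  1–3, exercising the missing-occasion bookkeeping. Default
  hyperparameters give mean occupancy ≈ 0.4 and mean per-occasion
  detection ≈ 0.5, so histories at $J = 3$ are informative but imperfect.

What the generator does **not** attempt: LiDAR point-cloud physics,
mechanistic mortality or fire spread, within-season dynamics, spatial
autocorrelation in occupancy beyond the covariates, or species
interactions. Its job is to produce data with the statistical structure
the estimators assume, plus enough mess (collinearity, imbalance,
missing occasions) to make the tests meaningful.

## 7. Problem sizes and reproducibility

The test suite exercises the sampler at a reduced but honest scale
(30 species × 150 sites × 3 occasions, 3 chains × 4 000 iterations with
1 000 burn-in, 20 replicates) and checks interval coverage of the
community means, $\hat R < 1.1$ everywhere, and the sign of the burned
effect. Oracles are independent re-implementations: latent-state
enumeration, 2-D grid integration, exhaustive subset search, a hand
Newton solver, and hand-computed closed forms. Every stochastic function
takes a `seed` argument and is bit-reproducible given it.
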