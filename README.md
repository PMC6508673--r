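# ghostbirds

Bird-community response to saltwater-driven "ghost forests", as a tested,
reusable R pipeline.

As sea level rises, saltwater intrusion kills low-lying coastal forest and
leaves *ghost forests*: stands of standing dead trees with strongly reduced
midstory (4.5–10 m) and canopy (20–30 m) vegetation density. `ghostbirds`
implements the full analysis chain for asking what that transition does to a
forest-bird community:

1. **Ghost-forest classification** — logistic regression on LiDAR-style
   vegetation-structure metrics with a correlation-constrained stepwise AIC
   selection, validated by holdout sensitivity/specificity
   (`stepwise_select()`, `evaluate_sensitivity_specificity()`).
2. **Hierarchical multi-species occupancy model** — detection/non-detection
   histories with imperfect detection; species-level coefficients as random
   effects under community hyperparameters; fit by an adaptive
   Metropolis-within-Gibbs sampler with latent-state augmentation and
   interweaving moves, written in C++ (`sample_posterior()`,
   `gelman_rubin()`, `classify_support()`).
3. **Community metrics** — latent-state species richness per site, richness
   regressions on vegetation metrics, and conservation-priority scoring of
   response groups (`richness_posterior()`, `group_pif_scores()`).
4. **Habitat-change accounting** — per-species occupancy predicted across
   two covariate epochs on a 48-m grid, differenced, thresholded at ±0.3,
   and converted to hectares of loss/gain within spatial strata
   (`stratified_change()`).
5. **Synthetic data** — a generator for two-epoch landscapes, masks, species
   parameters and repeat-survey detection histories with the statistical
   structure the analysis assumes, so everything runs and is testable
   without field data (`simulate_landscape()`, `simulate_detections()`).

The model, priors, numerical conventions and generator design are documented
in the methods vignette (`vignettes/methods.Rmd`).

## The model in brief

For species *k*, site *i*, occasion *j*:

```
z[i,k]   ~ Bernoulli(psi[i,k])            # latent occupancy
y[i,j,k] ~ Bernoulli(z[i,k] * p[i,j,k])   # imperfect detection

logit(p[i,j,k])  = a0[k] + aA[k]*routeA[i] + aB[k]*routeB[i]
logit(psi[i,k])  = b0[k] + b1[k]*mid[i] + b2[k]*canopy[i] + b3[k]*burned[i]
```

Each coefficient family is drawn from a community-level normal with mean
`mu ~ N(0, var 1000)` and sd `sigma ~ half-Normal(2.25)`. Intervals are
central 95% (type-7 quantiles of pooled post-burn-in thinned draws); an
effect is "strongly supported" when its interval excludes zero.

## Worked example

```r
library(ghostbirds)

# Two-epoch landscape with ghost transitions, a burned perimeter and
# low-lying forest; survey sites and a labelled metric table
land  <- simulate_landscape(dims = c(400, 400), seed = 11)
sites <- sample_sites(land, n_sites = 150, min_spacing = 200, seed = 101)
tab   <- sample_metric_table(land, n_points = 248, seed = 101)

# 1. Which metrics recognize ghost forest?
sel <- stepwise_select(tab)
sel$selected
#> [1] "dens_mid"   "max_height"
split <- split_train_validation(tab$ghost, seed = 1)
fit_cls <- stepwise_select(tab[split$train, ])
evaluate_sensitivity_specificity(fit_cls$fit, tab[split$validation, ])
#> # A tibble: 1 x 2
#>   sensitivity specificity
#>         <dbl>       <dbl>
#> 1       0.889       0.937

# 2. Fit the community occupancy model to simulated surveys
params <- draw_community_params(community_hyper(), n_species = 30,
                                seed = 301)
design <- site_design(land, sites)
y      <- simulate_detections(params, design, seed = 401)
fit    <- sample_posterior(y, design, chains = 3, n_iter = 4000,
                           n_burn = 1000, thin = 5, seed = 501)
fit
#> Hierarchical multi-species occupancy model fit
#>   30 species, 150 sites; 3 chain(s) x 4000 iterations (burn-in 1000, thin 5)
#>   mean Metropolis acceptance: detection 0.35, occupancy 0.36
max(gelman_rubin(fit)$rhat)
#> [1] 1.012065

# 3. Species richness and support classification
rich <- richness_posterior(fit)
range(rich$median)
#> [1]  3 23
cls <- classify_support(summarize_posterior(fit))
count_support_table(cls)
#> # A tibble: 4 x 5
#>   covariate        n_negative n_negative_strong n_positive n_positive_strong
#>   <chr>                 <int>             <int>      <int>             <int>
#> 1 b_canopy                  6                 0         24                13
#> 2 b_mid                     9                 1         21                13
#> 3 either covariate         14                 1         29                22
#> 4 both covariates           1                 0         16                 4

# 4. Hectares of habitat lost and gained per species and stratum
change <- stratified_change(land, fit, attr(design, "standardizers"))
head(change, 3)
#> # A tibble: 3 x 6
#>   species stratum    loss_ha gain_ha net_ha n_cells
#>     <dbl> <chr>        <dbl>   <dbl>  <dbl>   <int>
#> 1       1 whole_area   0.691       0 -0.691   10000
#> 2       1 burned       0           0  0        1411
#> 3       1 lowlying     0.691       0 -0.691    2800
```

(Numbers above are from this exact script; they are bit-reproducible under
the shown seeds on the same R/BLAS build.)

## Acceptance script

`scripts/acceptance.R` reruns the pipeline's main checks against
independent oracles — latent-state enumeration, 2-D grid integration,
exhaustive subset search, interval coverage across 20 MCMC replicates,
handcrafted change-accounting rasters, and the habitat sign contrast — and
writes the computed quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the run takes roughly ten minutes on
one CPU, most of it the recovery experiment.
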