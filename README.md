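# commoccu

Hierarchical multi-species occupancy modelling for camera-trap surveys of
rare and elusive wildlife communities — carnivores being the canonical
case. Camera traps detect such species infrequently and imperfectly, so
the fraction of stations with a photo ("naive occupancy") understates true
occurrence, often severely. `commoccu` corrects for that by modelling
occurrence and detection jointly across the whole community:

- occurrence: `z[i,j] ~ Bernoulli(psi[i,j])` for species *i* at station *j*;
- detection: `y[i,j] ~ Binomial(k[j], p[i,j] * z[i,j])` over `k[j]` trap-days;
- logit-linear covariate effects on both levels, with every species-level
  coefficient drawn from a community-level normal distribution
  (`alpha[c,i] ~ N(mu_c, sigma_c)`), and the occurrence/detection
  intercept pair bivariate normal with correlation `rho`;
- an optional auto-logistic spatial autocovariate (inverse-distance
  weighted occurrence of neighbours within 5 km);
- Bayesian model selection by community-level inclusion indicators
  (Kuo–Mallick) with prior inclusion probability 0.5, giving posterior
  inclusion probabilities per covariate and posterior probabilities per
  model, plus model-averaged estimates.

The package also builds the inputs: detection histories and effort from
raw photo/deployment records, and spatially explicit covariate indices
(quartic kernel density surfaces, catch-per-unit-effort ratios against
patrol effort, distance-to-feature, seasonal and integrated 16-day NDVI,
camera-based prey-biomass CPUE with a 5-minute deduplication rule,
fourth-root transform + standardization, collinearity screening). A
synthetic-data generator with known ground truth makes every stage
testable end to end. Inference runs in a bespoke Metropolis-within-Gibbs
sampler with the inner loop in C++ (Rcpp).

## Worked example

Simulate a frozen survey-scale scenario (9 species, 224 stations, ~5,000
trap-days) and fit the model with indicator-variable selection:

```r
library(commoccu)

sim <- paper_like_scenario()
d   <- sim$data
round(naive_occupancy(d), 3)
#> species_01 species_02 species_03 species_04 species_05 species_06
#>      0.353      0.013      0.080      0.263      0.554      0.125
#> species_07 species_08 species_09
#>      0.058      0.442      0.491

spec <- community_model_spec(
  occ_covariates = c("patrol", "edge", "river", "small_prey"),
  det_covariates = c("road", "team", "season"))
fit <- run_mcmc(d, sim$covariates, spec,
                mcmc_config(n_chains = 3, n_iter = 5000, n_burnin = 1000,
                            thin = 5, seed = 1),
                selection = TRUE)

round(inclusion_probabilities(fit), 3)
#>     w_occ_patrol       w_occ_edge      w_occ_river w_occ_small_prey
#>            1.000            0.644            1.000            1.000
#>       w_det_road       w_det_team     w_det_season
#>            1.000            1.000            0.414

render_model_table(fit, top = 3)[, 1:2]
#>                                                             model probability
#> 1          psi(patrol + edge + river + small_prey) p(road + team)   0.4146667
#> 2 psi(patrol + edge + river + small_prey) p(road + team + season)   0.2296667
#> 3        psi(patrol + river + small_prey) p(road + team + season)   0.1846667
```

The inclusion probabilities say how strongly the data support a
community-wide effect of each covariate (the planted strong small-prey
effect saturates at 1.0; the uninformative season effect hovers near its
0.5 prior). The model table ranks covariate combinations by their
posterior probability. Species-level summaries show the detectability
correction at work — posterior occurrence exceeds the naive fraction for
every species, dramatically so for the rare ones:

```r
head(render_species_table(d, fit)[, c("species", "naive", "psi", "p")], 3)
#>      species      naive        psi          p
#> 1 species_01 0.35267857 0.47922754 0.08241984
#> 2 species_02 0.01339286 0.04542161 0.03189524
#> 3 species_03 0.08035714 0.15621478 0.04896784

round(gelman_rubin(fit, c("mu_phi", "mu_eta", "rho")), 3)
#> mu_phi mu_eta    rho
#>  1.000  1.003  1.004
```

`naive_bias_report(d, fit)` quantifies the naive-measure bias per species
(a cross-species mean of +58% in this scenario), and
`predict_marginal_occurrence()` traces covariate response curves per
species.

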