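# msnmix

Hierarchical Bayesian estimation of the abundances of potentially
interacting species from repeated point counts — a multispecies N-mixture
model in which species abundances may be correlated through morphological
similarity, habitat covariates act on each species separately, and imperfect
detection is estimated from within-site replicate surveys.

The package is aimed at community ecologists analyzing point-count (or other
replicated count) surveys of a metacommunity — for example breeding-bird
counts across forest tracts — who want species-level abundance and
detectability estimates *and* a measure of residual association between
species after habitat effects are accounted for.

## The model

For species `i = 1..I`, site `k = 1..n`, visit `j = 1..J_k`:

    N_ik  ~ Poisson(lambda_ik),        log lambda_ik = beta0_i + x_k' beta_i
    beta0 ~ MVN(mu0 * 1, sigma0^2 R),  R_ij = exp(-d_ij / theta)
    beta_ip ~ Normal(mu_beta_p, sigma_beta_p^2)
    y_ijk | N_ik ~ Binomial(N_ik, p_i),  logit p_i = alpha0_i + v_i' alpha
    alpha0_i ~ Normal(mu_alpha, sigma_alpha^2)

`d_ij` is the Euclidean distance between species scores on the two leading
principal components of the correlation matrix of standardized morphological
traits; `theta > 0` controls how quickly correlation decays with trait
dissimilarity (`exp(-theta * d)` is available as an alternative
parameterization). Three correlation structures can be fitted and compared:
`independent` (R = I), `guild_block` (correlations only within foraging
guilds), and `full` (among all species). Fitting is by an adaptive
Metropolis-within-Gibbs sampler with exact discrete updates of the latent
abundances; competing structures are ranked by the Gelfand–Ghosh
posterior-predictive loss `D = penalty + lack-of-fit` (smaller is better).

## Worked example

Simulate a 50-site, 20-species, 3-visit community at the default design and
fit the full correlation structure:

```r
library(msnmix)
sim <- simulate_dataset(sim_design(), seed = 42)
fit <- fit_msnmix(sim$data, sim$meta, mode = "full",
                  site_transform = "none", detect_transform = "none",
                  control = mcmc_control(n_chains = 1, n_iter = 6000,
                                         n_burn = 2000, thin = 4, seed = 7))
summary(fit)
```

```
      parameter  mean   sd  q2.5 median  q97.5   mcse rhat
1           mu0 -0.14 1.41 -3.22 -0.057  2.513 0.0610    1
2        sigma0  2.08 0.61  1.14  1.996  3.478 0.0552    1
3         theta  2.43 1.18  0.27  2.501  4.331 0.0918    1
4      mu_alpha -1.69 0.30 -2.33 -1.669 -1.146 0.0307    1
5   sigma_alpha  0.89 0.23  0.52  0.869  1.433 0.0259    1
6    mu_beta_x1 -0.37 0.21 -0.82 -0.365  0.015 0.0091    1
7 sigma_beta_x1  0.83 0.16  0.57  0.819  1.211 0.0093    1
8      alpha_v1 -0.66 0.23 -1.12 -0.650 -0.243 0.0165    1
```

Every generating value (`mu0 = -0.75`, `sigma0 = 1.5`, `theta = 2`,
`mu_beta = -0.11`, `alpha = -0.63`, ...) lies inside its 95% credible
interval; `theta ≈ 2.4` recovers the simulated correlation range, and the
negative `alpha_v1` recovers the negative effect of the sound-power
covariate on detectability. Pairwise correlation estimates come from pushing
the `theta` draws through the correlation function:

```r
head(correlation_summary(fit), 3)
#>   species_i species_j   d same_guild    q2.5 median q97.5
#> 1      sp01      sp02 2.5      FALSE 8.7e-05   0.36  0.56
#> 2      sp01      sp03 1.6      FALSE 2.2e-03   0.52  0.68
#> 3      sp02      sp03 1.6      FALSE 2.3e-03   0.52  0.68
```

and the predictive loss of the fitted model is

```r
ppl(fit)
#> posterior-predictive loss: D = 3363.220 (penalty 2038.387 + lack of fit 1324.833), 3000 cells
```

`latent_summary()` gives per-cell abundance estimates,
`significant_effects()` flags species whose habitat effect's 95% interval
excludes zero, and `ppl_compare()` ranks several fitted structures.

A command-line interface wrapping the same functions (subcommands
`simulate`, `traits`, `corr`, `fit`, `compare`, each writing a JSON run
manifest) is installed at `inst/cli/msnmix.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "msnmix.R", package = "msnmix"))')" \
    simulate --seed 1 --out sim_out
```

## Data formats

Counts are read from CSV in either long format (`site, visit, species,
count`) or wide format (`site, visit`, one column per species), with a
configurable column mapping (`survey_layout()`); site covariates and the
species table (traits, guild, detection covariates) are plain CSV as well.
Missing visits are encoded by their absence (a visit mask), never as zero
counts. `write_survey()` / `write_sim()` emit the same dialects, and
round-trip exactly.
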