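# rangecast

Dynamic occupancy modelling and forecasting of species range expansion
on a gridded landscape.

Large ungulates (sika deer, wild boar and their analogues) have been
re-expanding across developed landscapes for decades. National
presence/absence surveys describe that expansion on a coarse lattice
(typically 5-km cells) at a handful of irregularly spaced occasions, and
managers need forward projections of where the species will be decades
ahead. `rangecast` implements the two-state dynamic occupancy model this
kind of analysis is built on, for quantitative ecologists who want a
tested, reproducible pipeline: synthetic data with known truth, Bayesian
fitting, convergence diagnostics, in-sample checking and Monte-Carlo
forecasting.

## The model

Cell occupancy evolves by a persistence/colonization process. For cell
*i* between occasions *k−1* and *k*,

    z_{i,k} = z_{i,k-1} · φ_i + (1 − z_{i,k-1}) · γ_{i,k}

where φ is the probability an occupied cell stays occupied over the
interval and γ the probability an empty cell is colonized. Both are
complementary log-log hazards with the survey interval `T_k` (years) as
an offset, so occasions 25 and 11 years apart share one coefficient
scale:

    φ_i     = 1 − exp(−exp(α_φ + β'x_i) · T_k)
    γ_{i,k} = 1 − exp(−exp(α_γ + β'x_{i,k} + β_d · D_{i,k}) · T_k)

`x` holds standardized environmental covariates (human population,
forest area, elevation, snow days, road area); `D_{i,k}` is the distance
from cell *i* to the nearest occupied cell at the interval start — zero
for occupied cells — recomputed from the current binary pattern at every
transition. This distance term is the model's stand-in for dispersal
limitation and spatial autocorrelation, and it is excluded from φ by
construction. A final presence-only survey occasion (only newly expanded
cells reported) enters the likelihood as colonization information only.

Coefficients get vague Normal(0, 1000) priors and are sampled by
adaptive Metropolis-within-Gibbs (per-coordinate plus per-component
adaptive-covariance block proposals, adaptation frozen after burn-in);
missing covariate entries are imputed as latent values with a
Uniform(0, 100) hyperprior on their standard deviation. Convergence is
judged by split-chain Gelman–Rubin R̂ < 1.1.

## Worked example

```r
library(rangecast)

# a 30 x 30 lattice of 5-km cells, three occasions (1978/2003/2014,
# the last presence-only), known truth coefficients
design <- simulation_design(n_x = 30, n_y = 30, seed = 1,
                            coeffs = recovery_true_coefficients(),
                            initial = list(type = "disc", centre = "corner",
                                           radius_km = 100))
ls  <- generate_covariates(design)
sim <- simulate_dynamics(ls, design)
survey <- censor_to_survey(sim$history, design)

draws <- fit_mcmc(survey, ls, mcmc_config(seed = 1))
subset(summarize_posterior(draws), grepl("gamma", parameter))
#>          parameter     median           lo          hi significant
#> 7  gamma_intercept -3.9967808 -4.198186816 -3.80887161        TRUE
#> 8  gamma_human_pop -0.3006968 -0.430288034 -0.18068267        TRUE
#> 9     gamma_forest  0.3071472  0.199396234  0.41096316        TRUE
#> 10 gamma_elevation -0.1738580 -0.315787648 -0.03425246        TRUE
#> 11 gamma_snow_days  0.3507751  0.217364411  0.48833530        TRUE
#> 12      gamma_road  0.1312214  0.007406669  0.25305388        TRUE
#> 13  gamma_distance -3.1348899 -3.492937039 -2.80908208        TRUE

max(compute_rhat(draws)$rhat)        # 1.006872 — all chains converged
correct_response_rate(draws, survey, ls)   # 0.8606419
```

The colonization medians sit on the simulated truth (intercept −4,
distance slope −3, the dominant negative effect, and mild environmental
slopes −0.26/0.23/−0.15/0.22/0.05); `significant` flags intervals
excluding zero. The in-sample one-step-ahead correct response rate is
0.86 here because this truth deliberately keeps hazards soft; with
sharply separated hazards it approaches 1 (see
`scripts/acceptance.R`). Forecasts then project the fitted process
forward, resampling binary maps per posterior draw and recomputing the
distance layer at every step:

```r
state <- sim$history[, 3]
scen  <- scenario_from_trend(ls, c(2025, 2050, 2100),
                             trends = list(human_pop = -0.005))
fc <- run_forecast(draws, ls, state, scen, n_draws = 300, seed = 4)
aggregate(mean_prob ~ year, fc, mean)
#>   year mean_prob
#> 1 2025 0.7249852
#> 2 2050 0.9025926
#> 3 2100 0.9680778
```

i.e. mean occupancy rises from ~61% of cells at the last survey to ~97%
by 2100 under this scenario. `run_pipeline()` chains all of the above
(simulate/load → screen → fit → R̂ gate → forecast) from one YAML config
with a digest-carrying manifest.

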