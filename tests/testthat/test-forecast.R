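frozen_coefficients <- function() {
  coefficient_set(
    c(intercept = 700, human_pop = 0, forest = 0, elevation = 0,
      snow_days = 0, road = 0),
    c(intercept = 0, human_pop = 0, forest = 0, elevation = 0,
      snow_days = 0, road = 0, distance = -1e6))
}

test_that("a frozen range forecasts exactly the last survey state", {
  d <- simulation_design(n_x = 10, n_y = 10, seed = 2)
  ls <- generate_covariates(d)
  sim <- simulate_dynamics(ls, d)
  stats <- sim$stats
  # identity transform for distance: unoccupied cells sit >= 1 unit away
  stats$mean[stats$covariate == "distance"] <- 0
  stats$sd[stats$covariate == "distance"] <- 1
  state <- sim$history[, 3]
  draws <- posterior_from_coefficients(frozen_coefficients(), stats,
                                       n_draws = 4)
  scen <- scenario_from_trend(ls, c(2025, 2050, 2100))
  fc <- run_forecast(draws, ls, state, scen, n_draws = 4, seed = 1)
  for (yr in c(2025, 2050, 2100))
    expect_identical(fc$mean_prob[fc$year == yr], as.numeric(state))
  expect_true(all(fc$lo95 == fc$mean_prob & fc$hi95 == fc$mean_prob))
  # the annual-step mode freezes the same range year by year
  fa <- run_forecast(draws, ls, state, scen, n_draws = 2, seed = 1,
                     annual_step = TRUE)
  expect_identical(fa$mean_prob, rep(as.numeric(state), 3))
})

test_that("forecasts are reproducible from their seed and shrink with draws", {
  d <- simulation_design(n_x = 10, n_y = 10, seed = 3)
  ls <- generate_covariates(d)
  sim <- simulate_dynamics(ls, d)
  state <- sim$history[, 3]
  draws <- posterior_from_coefficients(default_true_coefficients(),
                                       sim$stats)
  scen <- scenario_from_trend(ls, c(2025, 2050))
  f1 <- run_forecast(draws, ls, state, scen, n_draws = 60, seed = 9)
  f2 <- run_forecast(draws, ls, state, scen, n_draws = 60, seed = 9)
  expect_identical(as.data.frame(f1), as.data.frame(f2))

  f3 <- run_forecast(draws, ls, state, scen, n_draws = 600, seed = 9)
  # Monte-Carlo band on the occupied-cell count shrinks roughly as
  # 1/sqrt(n_draws): compare spread of per-draw counts' mean
  se1 <- stats::sd(attr(f1, "counts")[1, ]) / sqrt(60)
  se3 <- stats::sd(attr(f3, "counts")[1, ]) / sqrt(600)
  expect_lt(se3, se1)

  expect_error(run_forecast(draws, ls, state,
                            scenario_from_trend(ls, 2025), start_year = 2030),
               "after the last survey year")
  expect_error(run_forecast(draws, ls, c(state[-1], 2), scen), "binary")
})

test_that("one forecast step reproduces the in-sample one-step prediction", {
  d <- simulation_design(n_x = 10, n_y = 10, seed = 6)
  ls <- generate_covariates(d)
  sim <- simulate_dynamics(ls, d)
  stats <- sim$stats
  cf <- default_true_coefficients()
  draws <- posterior_from_coefficients(cf, stats)
  # analytic one-step probability from occasion 2, exactly as the
  # in-sample check computes it
  covs <- coef_covariates(cf)
  Xs <- standardize(covariate_matrix(ls, 2003, covs), stats)$values
  dstd <- (sim$distance[, 2] - stats$mean[stats$covariate == "distance"]) /
    stats$sd[stats$covariate == "distance"]
  eta_g <- linear_predictor(cf$gamma, cbind(Xs, distance = dstd))
  eta_p <- linear_predictor(cf$phi, Xs)
  p_exp <- ifelse(sim$history[, 2] == 1,
                  interval_prob(eta_p, 11), interval_prob(eta_g, 11))
  # forecast from occasion 2 to 2014 under the fitting covariates
  scen <- scenario_series("insample", landscape(
    ls$cell_id, ls$x_km, ls$y_km,
    lapply(ls$covariates, function(v)
      if (is.matrix(v)) matrix(v[, "2003"], ncol = 1) else v), 2014))
  fc <- run_forecast(draws, ls, sim$history[, 2], scen, start_year = 2003,
                     n_draws = 3000, seed = 8)
  mc_se <- sqrt(p_exp * (1 - p_exp) / 3000)
  expect_true(all(abs(fc$mean_prob - p_exp) < 5 * mc_se + 1e-9))
})

test_that("pushing the occupied core away never raises colonization", {
  # a 1-d strip: colonization probability at each unoccupied cell must
  # be non-increasing when the core is translated further away, given
  # the negative distance coefficient
  n <- 40
  ls <- landscape(seq_len(n), x_km = seq_len(n) * 5, y_km = rep(0, n),
                  covariates = list(human_pop = matrix(rnorm(n), n),
                                    forest = matrix(rnorm(n), n),
                                    elevation = rnorm(n),
                                    snow_days = matrix(rnorm(n), n),
                                    road = matrix(rnorm(n), n)),
                  years = 2014)
  cf <- default_true_coefficients()
  covs <- coef_covariates(cf)
  stats <- data.frame(covariate = c(covs, "distance"),
                      mean = c(rep(0, 5), 30), sd = c(rep(1, 5), 20))
  Xs <- standardize(covariate_matrix(ls, 2014, covs), stats)$values
  p_for <- function(occupied) {
    dstd <- (nearest_occupied_distance(ls, occupied) - 30) / 20
    interval_prob(linear_predictor(cf$gamma, cbind(Xs, distance = dstd)), 11)
  }
  near <- as.integer(seq_len(n) <= 8)
  far <- as.integer(seq_len(n) <= 4)   # core shrunk back: all distances grow
  free <- near == 0                     # cells unoccupied in both patterns
  expect_true(all(p_for(far)[free] <= p_for(near)[free] + 1e-15))
})

test_that("correct response rate is exact on deterministic dynamics", {
  d <- simulation_design(n_x = 10, n_y = 10, seed = 2)
  ls <- generate_covariates(d)
  sim0 <- simulate_dynamics(ls, d)
  stats <- sim0$stats
  stats$mean[stats$covariate == "distance"] <- 0
  stats$sd[stats$covariate == "distance"] <- 1
  sim <- simulate_dynamics(ls, d, stats = stats)
  # under the frozen coefficients every transition is deterministic
  dd <- d; dd$coeffs <- frozen_coefficients()
  simf <- simulate_dynamics(ls, dd, stats = stats)
  sv <- censor_to_survey(simf$history, dd)
  draws <- posterior_from_coefficients(frozen_coefficients(), stats)
  expect_equal(correct_response_rate(draws, sv, ls), 1.0)
  expect_equal(correct_response_rate(draws, sv, ls, granularity = "cell"), 1.0)
})

test_that("a probability exactly at the threshold predicts absent", {
  n <- 30
  T_y <- 10
  ls <- landscape(seq_len(n), seq_len(n) * 5, rep(0, n),
                  list(c1 = matrix(0.5 * seq_len(n), n, 2)),
                  years = c(2000, 2000 + T_y))
  # slope-free gamma: every absent-start cell shares one probability
  cf <- coefficient_set(c(intercept = 0, c1 = 0),
                        c(intercept = log(log(2) / T_y), c1 = 0, distance = 0))
  stats <- data.frame(covariate = c("c1", "distance"), mean = c(0, 0),
                      sd = c(1, 1))
  sv <- occupancy_survey(c(2000, 2000 + T_y),
                         cbind(c(1, rep(0, n - 1)), c(1, rep(0, n - 1))),
                         rep("presence_absence", 2))
  draws <- posterior_from_coefficients(cf, stats)
  p_const <- interval_prob(cf$gamma[["intercept"]], T_y)
  # threshold at exactly the shared probability: ties predict absent,
  # which matches the all-absent outcomes -> everything correct
  expect_equal(correct_response_rate(draws, sv, ls, threshold = p_const), 1.0)
  # nudge the threshold below: the tie rule flips every gamma cell to
  # a (wrong) presence prediction, leaving only the persisting cell
  expect_equal(correct_response_rate(draws, sv, ls,
                                     threshold = p_const - 1e-9), 1 / n)
})

test_that("correct response rate equals a hand enumeration", {
  d <- simulation_design(n_x = 8, n_y = 8, seed = 12,
                         coeffs = recovery_true_coefficients(),
                         initial = list(type = "disc", centre = "corner",
                                        radius_km = 25))
  ls <- generate_covariates(d)
  sim <- simulate_dynamics(ls, d)
  sv <- censor_to_survey(sim$history, d)
  cf <- d$coeffs
  draws <- posterior_from_coefficients(cf, sim$stats)
  got <- correct_response_rate(draws, sv, ls)

  covs <- coef_covariates(cf)
  correct <- c()
  for (k in 1:2) {
    yr <- d$years[k]
    T_k <- d$years[k + 1] - d$years[k]
    Xs <- standardize(covariate_matrix(ls, yr, covs), sim$stats)$values
    dstd <- (sim$distance[, k] - sim$stats$mean[sim$stats$covariate == "distance"]) /
      sim$stats$sd[sim$stats$covariate == "distance"]
    for (i in seq_len(n_cells(ls))) {
      s <- sv$status[i, k]; e <- sv$status[i, k + 1]
      if (is.na(s)) next
      if (s == 1) {
        if (sv$occasion_type[k + 1] == "presence_only" || is.na(e)) next
        p <- interval_prob(linear_predictor(cf$phi, Xs[i, ]), T_k)
      } else {
        if (sv$occasion_type[k + 1] == "presence_only" && !(e %in% 1)) next
        if (is.na(e)) next
        p <- interval_prob(linear_predictor(
          cf$gamma, c(Xs[i, ], distance = dstd[i])), T_k)
      }
      correct <- c(correct, (p > 0.5) == (e == 1))
    }
  }
  expect_equal(got, mean(correct), tolerance = 1e-12)
})

test_that("scenario construction validates horizons and extrapolates trends", {
  ls <- small_landscape(6, 6, seed = 4)
  expect_error(scenario_from_trend(ls, c(2010, 2050)), "after the last")
  scen <- scenario_from_trend(ls, c(2025, 2050),
                              trends = list(human_pop = -0.01))
  hp14 <- ls$covariates$human_pop[, "2014"]
  expect_equal(scen$landscape$covariates$human_pop[, "2025"],
               hp14 * 0.99^11)
  expect_equal(scen$landscape$covariates$elevation, ls$covariates$elevation)
})
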