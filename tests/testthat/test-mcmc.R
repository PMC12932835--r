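make_fit_fixture <- function(seed = 5, n = 12) {
  d <- simulation_design(n_x = n, n_y = n, seed = seed,
                         coeffs = recovery_true_coefficients(),
                         initial = list(type = "disc", centre = "corner",
                                        radius_km = 35))
  ls <- generate_covariates(d)
  sim <- simulate_dynamics(ls, d)
  list(design = d, landscape = ls, sim = sim,
       survey = censor_to_survey(sim$history, d))
}

test_that("the sampler is bit-reproducible from its seed", {
  fx <- make_fit_fixture()
  cfg <- mcmc_config(n_chains = 2, burn_in = 200, sampling = 400, thin = 2,
                     seed = 77)
  d1 <- fit_mcmc(fx$survey, fx$landscape, cfg)
  d2 <- fit_mcmc(fx$survey, fx$landscape, cfg)
  expect_identical(d1$draws, d2$draws)
  expect_identical(dim(d1$draws), c(200L, 2L, 13L))
})

test_that("with no informative data the posterior reproduces the prior", {
  ls <- small_landscape(8, 8, seed = 3)
  # a fully uninformative survey: the presence-only round reports
  # nothing, and under the missing policy silence carries no signal
  sv <- occupancy_survey(c(1978, 2003),
                         cbind(rep(c(1, 0), 32), rep(NA, 64)),
                         c("presence_absence", "presence_only"))
  cfg <- mcmc_config(n_chains = 3, burn_in = 300, sampling = 2000, thin = 1,
                     seed = 11)
  expect_warning(expect_warning(
    draws <- fit_mcmc(sv, ls, cfg, policy = "missing"),
    "present-start"), "absent-start")
  m <- draws_matrix(draws)
  sds <- apply(m[, 1:13], 2, stats::sd)
  expect_true(all(abs(sds - sqrt(1000)) / sqrt(1000) < 0.1))
})

test_that("posterior moments match numerical integration on a toy model", {
  # two-parameter persistence posterior (intercept, one slope) checked
  # against grid quadrature of prior x likelihood
  set.seed(21)
  n <- 80
  x <- stats::rnorm(n, 5, 2)
  pres <- c(rep(1, 60), rep(0, 20))
  T_y <- 10
  xs <- (x - mean(x)) / stats::sd(x)
  eta_true <- -1.1 + 0.7 * xs
  y2 <- ifelse(pres == 1, stats::rbinom(n, 1, 1 - exp(-exp(eta_true) * T_y)),
               stats::rbinom(n, 1, 0.2))
  ls <- landscape(seq_len(n), x_km = seq_len(n) * 5, y_km = rep(0, n),
                  covariates = list(c1 = matrix(x, n, 2)),
                  years = c(2000, 2000 + T_y))
  sv <- occupancy_survey(c(2000, 2000 + T_y), cbind(pres, y2),
                         rep("presence_absence", 2))
  cfg <- mcmc_config(n_chains = 3, burn_in = 1000, sampling = 6000, thin = 2,
                     seed = 4)
  draws <- fit_mcmc(sv, ls, cfg)
  m <- draws_matrix(draws)

  # oracle: quadrature over the phi block with plain formulas; the
  # standardized covariate is recomputed exactly as the fit sees it
  xp <- xs[pres == 1]; yp <- y2[pres == 1]
  grid_a <- seq(-4, 1.5, length.out = 220)
  grid_b <- seq(-1.5, 3, length.out = 220)
  lp <- outer(grid_a, grid_b, Vectorize(function(a, b) {
    eta <- a + b * xp
    p <- 1 - exp(-exp(eta) * T_y)
    sum(log(ifelse(yp == 1, p, 1 - p))) +
      stats::dnorm(a, 0, sqrt(1000), log = TRUE) +
      stats::dnorm(b, 0, sqrt(1000), log = TRUE)
  }))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean_a <- sum(rowSums(w) * grid_a)
  mean_b <- sum(colSums(w) * grid_b)
  expect_lt(abs(mean(m[, "phi_intercept"]) - mean_a), 0.1)
  expect_lt(abs(mean(m[, "phi_c1"]) - mean_b), 0.1)
})

test_that("missing covariate entries are imputed as latent values", {
  fx <- make_fit_fixture(seed = 8)
  ls <- fx$landscape
  set.seed(1)
  holes <- sample(n_cells(ls), 20)
  ls$covariates$snow_days[holes, ] <- NA
  cfg <- mcmc_config(n_chains = 2, burn_in = 400, sampling = 800, thin = 2,
                     seed = 13)
  draws <- fit_mcmc(fx$survey, ls, cfg)
  expect_true("sigma_snow_days" %in% draws$parameters)
  m <- draws_matrix(draws)
  expect_true(all(is.finite(m)))
  expect_true(all(m[, "sigma_snow_days"] > 0 & m[, "sigma_snow_days"] < 100))
  # the data still identify the negative distance effect
  expect_gt(mean(m[, "gamma_distance"] < 0), 0.95)

  ls$covariates$snow_days[] <- NA
  expect_error(fit_mcmc(fx$survey, ls, cfg), "entirely missing")
})

test_that("thinning changes retention, not the distribution", {
  fx <- make_fit_fixture(seed = 9)
  cfg1 <- mcmc_config(n_chains = 3, burn_in = 600, sampling = 2400, thin = 1,
                      seed = 5)
  cfg5 <- mcmc_config(n_chains = 3, burn_in = 600, sampling = 2400, thin = 5,
                      seed = 6)
  s1 <- summarize_posterior(fit_mcmc(fx$survey, fx$landscape, cfg1))
  s5 <- summarize_posterior(fit_mcmc(fx$survey, fx$landscape, cfg5))
  g <- grepl("^gamma", s1$parameter)
  expect_lt(max(abs(s1$median[g] - s5$median[g])), 0.6)
})

test_that("quadrupling the cells tightens every gamma interval", {
  run_width <- function(n, seed) {
    fx <- make_fit_fixture(seed = seed, n = n)
    cfg <- mcmc_config(n_chains = 2, burn_in = 800, sampling = 1600, thin = 2,
                       seed = 3)
    s <- summarize_posterior(fit_mcmc(fx$survey, fx$landscape, cfg))
    mean((s$hi - s$lo)[grepl("^gamma", s$parameter)])
  }
  expect_lt(run_width(24, seed = 5), run_width(12, seed = 5))
})

test_that("the missing presence-only policy widens colonization intervals", {
  fx <- make_fit_fixture(seed = 10, n = 14)
  cfg <- mcmc_config(n_chains = 2, burn_in = 600, sampling = 1200, thin = 2,
                     seed = 21)
  s_abs <- summarize_posterior(fit_mcmc(fx$survey, fx$landscape, cfg,
                                        policy = "absent"))
  sv_na <- censor_to_survey(fx$sim$history, fx$design, policy = "missing")
  s_mis <- summarize_posterior(fit_mcmc(sv_na, fx$landscape, cfg,
                                        policy = "missing"))
  g <- grepl("^gamma", s_abs$parameter)
  expect_gt(mean((s_mis$hi - s_mis$lo)[g]), mean((s_abs$hi - s_abs$lo)[g]))
  # and the distance effect stays negative under both policies
  expect_lt(s_mis$hi[s_mis$parameter == "gamma_distance"], 0)
})

test_that("R-hat behaves at the converged and diverged limits", {
  set.seed(2)
  base <- stats::rnorm(1000)
  same <- cbind(base, sample(base))
  expect_lt(compute_rhat(same)$rhat, 1.01)
  shifted <- cbind(stats::rnorm(1000), stats::rnorm(1000, 5))
  expect_gt(compute_rhat(shifted)$rhat, 1.1)
  # degenerate chains are flagged, not crashed
  flat <- cbind(rep(1, 50), rep(1, 50))
  expect_true(is.na(compute_rhat(flat)$rhat))
  expect_error(compute_rhat(matrix(0, 50, 1)), ">= 2 chains")
  expect_error(compute_rhat(matrix(0, 4, 2)), ">= 10 retained")
})

test_that("R-hat matches the textbook formula on random chains", {
  set.seed(14)
  for (rep in 1:10) {
    mat <- matrix(stats::rnorm(3 * 200, sd = stats::runif(1, 0.5, 3)), 200, 3)
    mat[, 2] <- mat[, 2] + stats::runif(1, -1, 1)
    expect_equal(compute_rhat(mat)$rhat, oracle_rhat(mat), tolerance = 1e-10)
  }
})

test_that("posterior summaries are exact order statistics", {
  one <- array(2, c(50, 2, 1), dimnames = list(NULL, NULL, "a"))
  d <- structure(list(draws = one, parameters = "a"), class = "rc_draws")
  s <- summarize_posterior(d)
  expect_equal(unlist(s[, c("median", "lo", "hi")]), c(2, 2, 2),
               ignore_attr = TRUE)
  expect_true(s$significant)

  set.seed(3)
  sym <- array(stats::rnorm(2000), c(1000, 2, 1),
               dimnames = list(NULL, NULL, "a"))
  d2 <- structure(list(draws = sym, parameters = "a"), class = "rc_draws")
  s2 <- summarize_posterior(d2)
  expect_false(s2$significant)

  v <- stats::rnorm(10001)
  d3 <- structure(list(draws = array(v, c(10001, 1, 1),
                                     dimnames = list(NULL, NULL, "a")),
                       parameters = "a"), class = "rc_draws")
  s3 <- summarize_posterior(d3)
  sv <- sort(v)
  expect_equal(s3$median, sv[5001])
  expect_equal(s3$lo, sv[251])     # 0.025 * 10000 + 1: exact order statistic
  expect_equal(s3$hi, sv[9751])
})

test_that("mcmc_config validates its protocol", {
  expect_error(mcmc_config(n_chains = 1), ">= 2 chains")
  expect_error(mcmc_config(thin = 0), "invalid")
  expect_error(mcmc_config(rhat_threshold = 1), "exceed 1")
  heavy <- mcmc_config(preset = "survey")
  expect_identical(c(heavy$burn_in, heavy$sampling, heavy$thin),
                   c(50000L, 200000L, 15L))
})
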