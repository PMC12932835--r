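#' Scenario covariate series for forecasting
#'
#' Wraps a future landscape: an `rc_landscape` whose `years` are the
#' forecast horizon years and whose time-varying layers hold the
#' scenario's covariate values at those years (static layers, e.g.
#' elevation, are carried unchanged).
#'
#' @param label scenario name (e.g. a climate-pathway analogue).
#' @param future an `rc_landscape` with horizon years.
#' @return object of class `rc_scenario`.
#' @export
scenario_series <- function(label, future) {
  stopifnot(inherits(future, "rc_landscape"))
  if (length(future$years) < 1 || any(diff(future$years) <= 0))
    stop("horizon years must be strictly increasing")
  structure(list(label = label, landscape = future, years = future$years),
            class = "rc_scenario")
}

#' Build a simple trend scenario from a fitted landscape
#'
#' Each time-varying covariate is extrapolated from its last-survey-year
#' layer with a constant multiplicative annual trend (e.g. -0.005 for a
#' 0.5%/year decline in human population). A deliberately simple
#' stand-in for externally modelled scenario products.
#'
#' @param landscape the fitting `rc_landscape`.
#' @param horizons strictly increasing horizon years (all after the last
#'   landscape year).
#' @param trends named list/vector of annual rates per covariate;
#'   covariates not named get rate 0.
#' @param label scenario name.
#' @return an `rc_scenario`.
#' @export
scenario_from_trend <- function(landscape, horizons,
                                trends = list(), label = "trend") {
  last_year <- max(landscape$years)
  horizons <- as.integer(horizons)
  if (any(horizons <= last_year))
    stop("horizons must all lie after the last survey year ", last_year)
  covs <- list()
  for (nm in names(landscape$covariates)) {
    v <- landscape$covariates[[nm]]
    if (!is.matrix(v)) { covs[[nm]] <- v; next }
    base <- v[, as.character(last_year)]
    rate <- if (nm %in% names(trends)) trends[[nm]] else 0
    m <- vapply(horizons, function(y) base * (1 + rate)^(y - last_year),
                numeric(length(base)))
    covs[[nm]] <- m
  }
  future <- landscape(landscape$cell_id, landscape$x_km, landscape$y_km,
                      covs, horizons)
  scenario_series(label, future)
}

# covariate matrix at an interval-start year, taken from the scenario
# when it has a layer there and from the fitting landscape otherwise
lookup_covariates <- function(year, scenario, landscape, covs) {
  if (year %in% scenario$landscape$years)
    covariate_matrix(scenario$landscape, year, covs)
  else covariate_matrix(landscape, year, covs)
}

#' Forward Monte-Carlo occupancy forecast
#'
#' For each of `n_draws` posterior samples a binary occupancy trajectory
#' is simulated horizon to horizon from the last survey state: at every
#' step the distance-to-nearest-occupied layer is recomputed from the
#' current binary pattern, covariates at the interval-start year are
#' standardized with the *fitting* stats, persistence and colonization
#' probabilities are evaluated with the gap in years as the hazard
#' offset, and each cell's next state is drawn Bernoulli. Binary-state
#' resampling (rather than probability propagation) is required because
#' the distance covariate is a nonlinear function of the binary pattern.
#'
#' @param draws an `rc_draws` (fitted posterior, or
#'   [posterior_from_coefficients()]).
#' @param landscape the fitting `rc_landscape` (supplies interval-start
#'   covariates for the first step).
#' @param last_state fully binary occupancy vector at the last survey
#'   (resolve a presence-only round first; see the presence-only policy
#'   notes in [log_likelihood()]).
#' @param scenario an `rc_scenario`.
#' @param start_year year of `last_state` (default: last landscape year).
#' @param n_draws number of posterior samples / trajectories.
#' @param seed seed for draw selection and trajectory noise.
#' @param annual_step if `TRUE`, the process is stepped one year at a
#'   time (offset T = 1) between horizons instead of horizon to
#'   horizon, with covariates held at the most recent available layer.
#'   The two modes give different trajectories because the distance
#'   covariate reacts to every intermediate pattern in annual mode.
#' @return object of class `rc_forecast`: a data frame (cell_id,
#'   scenario, year, mean_prob, lo95, hi95) with per-draw occupied-cell
#'   counts in `attr(, "counts")` (horizons x draws).
#' @export
run_forecast <- function(draws, landscape, last_state, scenario,
                         start_year = max(landscape$years),
                         n_draws = 500, seed = 1, annual_step = FALSE) {
  covs <- draws$covariates
  miss <- setdiff(covs, names(landscape$covariates))
  if (length(miss))
    stop("posterior/landscape covariate mismatch: ",
         paste(miss, collapse = ", "))
  if (any(scenario$years <= start_year))
    stop("forecast horizons must lie after the last survey year ", start_year)
  if (!all(last_state %in% c(0, 1)))
    stop("last_state must be fully binary (resolve presence-only cells first)")
  stats <- draws$stats
  phi_form <- draws$phi_form
  n <- n_cells(landscape)
  horizons <- scenario$years
  H <- length(horizons)

  B <- draws_matrix(draws)
  set.seed(stage_seed(seed, "draw_select"))
  sel <- sample.int(nrow(B), n_draws, replace = TRUE)

  phi_names <- paste0("phi_", c("intercept", covs))
  gam_names <- paste0("gamma_", c("intercept", covs, "distance"))

  # step schedule: horizon-to-horizon gaps, or single years in annual
  # mode; each step carries its target year and its offset in years
  targets <- if (annual_step) seq(start_year + 1L, horizons[H]) else horizons
  step_T <- diff(c(start_year, targets))
  record_at <- match(horizons, targets)

  # standardized covariate matrices per interval-start year, shared by
  # all draws (only the distance layer is state-dependent); interval
  # starts use the most recent available layer
  available <- sort(unique(c(start_year, scenario$landscape$years)))
  step_start <- c(start_year, targets[-length(targets)])
  layer_year <- vapply(step_start, function(y) max(available[available <= y]),
                       numeric(1))
  Xs_by_step <- lapply(layer_year, function(y)
    standardize(lookup_covariates(y, scenario, landscape, covs), stats)$values)
  di <- match("distance", stats$covariate)

  occ <- array(NA_integer_, c(n, H, n_draws))
  for (d in seq_len(n_draws)) {
    b <- B[sel[d], ]
    bphi <- stats::setNames(b[phi_names], c("intercept", covs))
    bgam <- stats::setNames(b[gam_names], c("intercept", covs, "distance"))
    state <- as.integer(last_state)
    for (h in seq_along(targets)) {
      T_h <- step_T[h]
      # an extinct range has no defined distance layer; use the
      # landscape diagonal (every cell is maximally far from the front)
      d_raw <- if (any(state == 1)) nearest_occupied_distance(landscape, state)
        else rep(sqrt(diff(range(landscape$x_km))^2 +
                        diff(range(landscape$y_km))^2), n)
      dist_std <- (d_raw - stats$mean[di]) / stats$sd[di]
      X <- cbind(Xs_by_step[[h]], distance = dist_std)
      eta_phi <- linear_predictor(bphi, Xs_by_step[[h]])
      eta_gam <- linear_predictor(bgam, X)
      p <- ifelse(state == 1, phi_prob(eta_phi, T_h, phi_form),
                  interval_prob(eta_gam, T_h))
      set.seed(stage_seed(seed, sprintf("traj_%d_%d", d, h)))
      state <- as.integer(stats::runif(n) < p)
      if (h %in% record_at) occ[, which(record_at == h), d] <- state
    }
  }

  agg <- lapply(seq_len(H), function(h) {
    m <- matrix(occ[, h, ], nrow = n)
    q <- apply(m, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(cell_id = landscape$cell_id, scenario = scenario$label,
               year = horizons[h], mean_prob = rowMeans(m),
               lo95 = q[1, ], hi95 = q[2, ])
  })
  out <- do.call(rbind, agg)
  counts <- matrix(apply(occ, c(2, 3), sum), H, n_draws)
  rownames(counts) <- horizons
  structure(out, counts = counts, n_draws = n_draws, seed = seed,
            class = c("rc_forecast", "data.frame"))
}

#' In-sample one-step-ahead correct response rate
#'
#' For every evaluable transition in the fitting data the one-step-ahead
#' occupancy probability (posterior mean of phi for start-present cells,
#' of gamma for start-absent cells) is dichotomized at `threshold` and
#' compared with the observed end state. Presence-only occasions are
#' evaluated on their reported newly present cells only. Ties
#' (probability exactly at the threshold) predict absent.
#'
#' @param draws an `rc_draws`.
#' @param survey the fitting `rc_survey`.
#' @param landscape the fitting `rc_landscape` (natural scale).
#' @param threshold probability cut (default 0.5).
#' @param granularity `"transition"` (proportion of correct
#'   cell-occasions, the default) or `"cell"` (proportion of cells all
#'   of whose transitions are correct).
#' @param max_draws cap on posterior draws used for the predicted
#'   probabilities (evenly thinned).
#' @return proportion correct in \[0, 1\].
#' @export
correct_response_rate <- function(draws, survey, landscape, threshold = 0.5,
                                  granularity = c("transition", "cell"),
                                  max_draws = 500) {
  granularity <- match.arg(granularity)
  covs <- draws$covariates
  stats <- draws$stats
  dist_raw <- survey_distance_layers(survey, landscape)
  di <- match("distance", stats$covariate)
  dist_std <- (dist_raw - stats$mean[di]) / stats$sd[di]
  ls_std <- standardize_landscape(landscape, stats, covs)
  blocks <- transition_blocks(survey, ls_std, dist_std, covs, draws$policy)

  B <- draws_matrix(draws)
  if (nrow(B) > max_draws)
    B <- B[round(seq(1, nrow(B), length.out = max_draws)), , drop = FALSE]

  eval_block <- function(block, comp) {
    if (!length(block$y)) return(NULL)
    po <- survey$occasion_type[block$interval + 1L] == "presence_only"
    keep <- !po | block$y == 1
    if (!any(keep)) return(NULL)
    X <- cbind(1, block$X)[keep, , drop = FALSE]
    T_b <- block$T[keep]
    nm <- if (comp == "phi") paste0("phi_", c("intercept", covs))
          else paste0("gamma_", c("intercept", covs, "distance"))
    eta <- X %*% t(B[, nm, drop = FALSE])
    p <- if (comp == "phi") phi_prob(eta, T_b, draws$phi_form)
         else interval_prob(eta, T_b)
    pm <- rowMeans(p)
    data.frame(cell = block$cell[keep],
               correct = (pm > threshold) == (block$y[keep] == 1))
  }
  res <- rbind(eval_block(blocks$phi, "phi"), eval_block(blocks$gamma, "gamma"))
  if (is.null(res) || !nrow(res)) stop("no evaluable cell-occasions")
  if (granularity == "transition") mean(res$correct)
  else mean(tapply(res$correct, res$cell, all))
}
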