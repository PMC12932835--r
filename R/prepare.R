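# Shared data-preparation helpers for fitting, prediction and forecasting.

# Standardize every covariate layer of a landscape with the given stats
# (NA entries propagate; they become latent values in the sampler).
standardize_landscape <- function(landscape, stats,
                                  covariates = names(landscape$covariates)) {
  out <- landscape
  for (nm in covariates) {
    v <- landscape$covariates[[nm]]
    i <- match(nm, stats$covariate)
    if (is.na(i)) stop("no standardization stats for covariate '", nm, "'")
    out$covariates[[nm]] <- (v - stats$mean[i]) / stats$sd[i]
  }
  out
}

# Raw-km distance layers at each interval-start occasion, computed from
# the survey's observed presences (NA treated as not occupied for the
# purpose of the distance layer). Column k = layer at occasion k; the
# final column is filled too when the occasion has any presence.
survey_distance_layers <- function(survey, landscape) {
  K <- length(survey$years)
  d <- matrix(NA_real_, n_cells(landscape), K,
              dimnames = list(NULL, survey$years))
  for (k in seq_len(K)) {
    occ <- !is.na(survey$status[, k]) & survey$status[, k] == 1
    if (any(occ)) d[, k] <- nearest_occupied_distance(landscape, occ)
  }
  d
}

# Fitting-period standardization stats: first-occasion covariate layers
# plus the first-occasion distance layer. This is the one policy the
# simulator and the fitting path share (see the methods vignette).
fit_stats <- function(landscape, first_year, distance_first,
                      covariates = names(landscape$covariates),
                      distance_name = "distance") {
  X1 <- cbind(covariate_matrix(landscape, first_year, covariates),
              distance_first)
  colnames(X1) <- c(covariates, distance_name)
  standardize(X1)$stats
}

# Resolve a survey's final occasion to a fully binary state vector for
# forecasting: a presence-only round keeps its reported presences and
# falls back to the previous occasion's state for unreported cells.
resolve_last_state <- function(survey) {
  K <- length(survey$years)
  s <- survey$status[, K]
  if (survey$occasion_type[K] == "presence_only") {
    prev <- survey$status[, K - 1]
    s <- ifelse(!is.na(s) & s == 1, 1, prev)
  }
  if (anyNA(s))
    stop("cannot resolve a fully binary last-survey state: NA cells remain")
  as.integer(s)
}
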