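#' Simulation design for the synthetic landscape generator
#'
#' Describes a rectangular cell lattice, the survey occasions, the true
#' coefficient set driving the occupancy dynamics, the spatial smoothness
#' of the covariate fields and the initially occupied region. The
#' defaults mirror the structure of the national ungulate surveys the
#' model targets: a 5-km lattice, occasions 1978 / 2003 / 2014 (so
#' intervals of 25 and 11 years) with the final occasion presence-only,
#' and truth coefficients with near-certain persistence and a strongly
#' negative distance effect on colonization.
#'
#' @param n_x,n_y grid dimensions in cells.
#' @param edge_km cell edge length (km).
#' @param years survey occasion years (strictly increasing, >= 2).
#' @param coeffs true `rc_coefficients` (standardized scale).
#' @param bandwidth Gaussian smoothing bandwidth of the covariate random
#'   fields, in cells; 0 gives i.i.d. white-noise fields.
#' @param initial initially occupied region: either
#'   `list(type = "disc", centre = "corner" or c(x, y), radius_km = r)`
#'   or `list(type = "state", state = <binary vector>)`.
#' @param elevation_gradient logical; add a deterministic south-to-north
#'   elevation ramp on top of the smooth noise field.
#' @param phi_form persistence parameterization (see [log_likelihood()]).
#' @param seed master seed; every random draw in the generator derives
#'   from it.
#' @return object of class `rc_design`.
#' @export
simulation_design <- function(n_x = 50, n_y = 50, edge_km = 5,
                              years = c(1978, 2003, 2014),
                              coeffs = default_true_coefficients(),
                              bandwidth = 3,
                              initial = list(type = "disc", centre = "corner",
                                             radius_km = 20),
                              elevation_gradient = TRUE,
                              phi_form = "as_printed",
                              seed = 1) {
  if (n_x <= 0 || n_y <= 0) stop("grid dimensions must be positive")
  if (length(years) < 2 || any(diff(years) <= 0))
    stop("need >= 2 strictly increasing occasion years")
  stopifnot(inherits(coeffs, "rc_coefficients"))
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 edge_km = edge_km, years = as.integer(years),
                 coeffs = coeffs, bandwidth = bandwidth, initial = initial,
                 elevation_gradient = elevation_gradient,
                 phi_form = phi_form, seed = as.integer(seed)),
            class = "rc_design")
}

# Separable Gaussian smoothing of a matrix field, with edge
# renormalization so border cells are not damped. bandwidth in cells.
gaussian_smooth <- function(M, bandwidth) {
  if (bandwidth <= 0) return(M)
  half <- max(1L, ceiling(3 * bandwidth))
  w <- stats::dnorm(seq(-half, half), sd = bandwidth)
  smooth1 <- function(A) {
    n <- nrow(A)
    out <- matrix(0, n, ncol(A))
    wsum <- numeric(n)
    for (j in seq_along(w)) {
      off <- j - half - 1L
      rows <- seq_len(n) + off
      ok <- rows >= 1L & rows <= n
      out[ok, ] <- out[ok, ] + w[j] * A[rows[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + w[j]
    }
    out / wsum
  }
  t(smooth1(t(smooth1(M))))
}

# One smoothed standard-normal field as a vector in cell order
# (x index fastest), rescaled to mean 0 / sd 1 after smoothing.
random_field <- function(n_x, n_y, bandwidth, seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(n_x * n_y), nrow = n_x, ncol = n_y)
  M <- gaussian_smooth(M, bandwidth)
  v <- as.vector(M)
  (v - mean(v)) / stats::sd(v)
}

# location/scale used to map unit fields onto covariate-like ranges;
# values only matter cosmetically because everything is standardized
# before entering the model.
field_scales <- list(
  human_pop = c(mean = 800, sd = 600),
  forest    = c(mean = 15,  sd = 5),
  elevation = c(mean = 400, sd = 250),
  snow_days = c(mean = 30,  sd = 15),
  road      = c(mean = 1,   sd = 0.5))

#' Generate a synthetic landscape of smooth covariate fields
#'
#' Every covariate surface is white noise convolved with a Gaussian
#' kernel of the design's bandwidth (bandwidth 0 gives an i.i.d. field).
#' Elevation is static, optionally with a deterministic ramp;
#' time-varying covariates evolve between occasions by adding a small
#' smooth increment (one tenth of the field scale). Fully reproducible
#' from the design seed.
#'
#' @param design an `rc_design`.
#' @return an `rc_landscape` with one layer per occasion year for the
#'   time-varying covariates.
#' @export
generate_covariates <- function(design) {
  n_x <- design$n_x; n_y <- design$n_y
  n <- n_x * n_y
  ix <- rep(seq_len(n_x), times = n_y)
  iy <- rep(seq_len(n_y), each = n_x)
  x_km <- (ix - 0.5) * design$edge_km
  y_km <- (iy - 0.5) * design$edge_km

  covs <- list()
  cov_names <- coef_covariates(design$coeffs)
  for (nm in cov_names) {
    sc <- field_scales[[nm]]
    if (is.null(sc)) sc <- c(mean = 0, sd = 1)
    base <- random_field(n_x, n_y, design$bandwidth,
                         stage_seed(design$seed, paste0("cov_", nm)))
    if (nm == "elevation") {
      if (isTRUE(design$elevation_gradient))
        base <- 0.5 * base + 1.5 * (iy - mean(iy)) / stats::sd(iy)
      covs[[nm]] <- sc["mean"] + sc["sd"] * base
      names(covs[[nm]]) <- NULL
    } else {
      m <- matrix(NA_real_, n, length(design$years))
      layer <- base
      for (k in seq_along(design$years)) {
        if (k > 1) {
          inc <- random_field(n_x, n_y, design$bandwidth,
                              stage_seed(design$seed, paste0("inc_", nm, "_", k)))
          layer <- layer + 0.1 * inc
        }
        m[, k] <- sc["mean"] + sc["sd"] * layer
      }
      covs[[nm]] <- m
    }
  }
  landscape(seq_len(n), x_km, y_km, covs, design$years)
}

# resolve the design's initial region to a 0/1 vector
initial_state <- function(landscape, design) {
  init <- design$initial
  if (identical(init$type, "state")) {
    z <- as.integer(as.logical(init$state))
    if (length(z) != n_cells(landscape))
      stop("initial state length must match the number of cells")
  } else if (identical(init$type, "disc")) {
    ctr <- init$centre
    if (identical(ctr, "corner"))
      ctr <- c(min(landscape$x_km), min(landscape$y_km))
    z <- as.integer((landscape$x_km - ctr[1])^2 +
                      (landscape$y_km - ctr[2])^2 <= init$radius_km^2)
  } else stop("unknown initial region type: ", init$type)
  if (!any(z == 1)) stop("initial occupied region is empty")
  z
}

#' Simulate the occupancy dynamics forward under known coefficients
#'
#' Occasion 1 is set from the design's initial region. For each later
#' occasion the distance-to-nearest-occupied layer is recomputed from
#' the current binary pattern, covariates (distance included) are
#' standardized with the first-occasion stats, persistence and
#' colonization probabilities are evaluated with the inter-occasion gap
#' in years as the hazard offset, and each cell's next state is drawn
#' Bernoulli. Draws for each occasion come from their own derived seed,
#' so per-occasion reproducibility does not depend on traversal order.
#'
#' The same standardization (first-occasion covariate and distance
#' layers) is the default on the fitting path, which is what makes
#' recovered coefficients directly comparable with the truth here.
#'
#' @param landscape an `rc_landscape` on the natural covariate scale.
#' @param design the `rc_design` that generated it.
#' @param stats optional standardization stats to use instead of the
#'   first-occasion stats (must cover all covariates plus the distance
#'   term).
#' @return list with `history` (`n_cells x n_occasions` 0/1 matrix),
#'   `distance` (per-occasion raw-km distance layers, same shape),
#'   `stats` (the standardization stats used) and `design`.
#' @export
simulate_dynamics <- function(landscape, design, stats = NULL) {
  years <- design$years
  K <- length(years)
  if (any(diff(years) <= 0)) stop("non-positive inter-occasion interval")
  n <- n_cells(landscape)
  covs <- coef_covariates(design$coeffs)
  dn <- design$coeffs$distance_name

  z <- matrix(0L, n, K, dimnames = list(NULL, years))
  dist_km <- matrix(NA_real_, n, K, dimnames = list(NULL, years))
  z[, 1] <- initial_state(landscape, design)
  dist_km[, 1] <- nearest_occupied_distance(landscape, z[, 1])

  if (is.null(stats)) {
    X1 <- cbind(covariate_matrix(landscape, years[1], covs),
                dist_km[, 1, drop = FALSE])
    colnames(X1) <- c(covs, dn)
    stats <- standardize(X1)$stats
  }

  for (k in 2:K) {
    T_k <- years[k] - years[k - 1]
    X <- covariate_matrix(landscape, years[k - 1], covs)
    Xs <- standardize(X, stats)$values
    dcol <- matrix(dist_km[, k - 1], ncol = 1, dimnames = list(NULL, dn))
    dcol_s <- standardize(dcol, stats)$values
    eta_phi <- linear_predictor(design$coeffs$phi, Xs)
    eta_gam <- linear_predictor(design$coeffs$gamma, cbind(Xs, dcol_s))
    p_phi <- phi_prob(eta_phi, T_k, design$phi_form)
    p_gam <- interval_prob(eta_gam, T_k)
    p_next <- ifelse(z[, k - 1] == 1, p_phi, p_gam)
    set.seed(stage_seed(design$seed, paste0("dyn_", k)))
    z[, k] <- as.integer(stats::runif(n) < p_next)
    dist_km[, k] <- if (any(z[, k] == 1))
      nearest_occupied_distance(landscape, z[, k]) else NA_real_
  }
  list(history = z, distance = dist_km, stats = stats, design = design)
}

#' Censor a complete occupancy history to the survey's reporting scheme
#'
#' All occasions except the last are emitted verbatim as
#' presence/absence. The final occasion becomes presence-only: only
#' cells newly present relative to the previous occasion are reported
#' as present (a cell already present before is *not* re-reported);
#' every other cell is marked 0 under `policy = "absent"` or NA under
#' `policy = "missing"`. Deterministic given the history.
#'
#' @param history `n_cells x n_occasions` 0/1 matrix from
#'   [simulate_dynamics()].
#' @param design the `rc_design` (supplies occasion years).
#' @param policy how unreported cells are encoded.
#' @return an `rc_survey`.
#' @export
censor_to_survey <- function(history, design, policy = c("absent", "missing")) {
  policy <- match.arg(policy)
  K <- ncol(history)
  if (K < 3)
    stop("presence-only censoring needs at least 3 occasions")
  status <- history
  storage.mode(status) <- "integer"
  newly <- history[, K] == 1 & history[, K - 1] == 0
  status[, K] <- ifelse(newly, 1L,
                        if (policy == "absent") 0L else NA_integer_)
  occupancy_survey(design$years, status,
                   c(rep("presence_absence", K - 1), "presence_only"))
}
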