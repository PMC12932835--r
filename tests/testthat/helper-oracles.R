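# Independent oracles and fixture builders. Everything here is written
# against the model's definitions directly (scalar loops, plain
# formulas), never by calling the implementation paths it checks.

# term-by-term enumeration of the observed-data log-likelihood
oracle_loglik <- function(status, types, years, X_by_interval, dist_by_occ,
                          phi, gamma, policy, phi_form = "as_printed") {
  total <- 0
  K <- length(years)
  for (k in seq_len(K - 1)) {
    T_k <- years[k + 1] - years[k]
    for (i in seq_len(nrow(status))) {
      s <- status[i, k]; e <- status[i, k + 1]
      if (is.na(s)) next
      x <- X_by_interval[[k]][i, ]
      if (s == 1) {
        if (types[k + 1] == "presence_only") next
        if (is.na(e)) next
        eta <- phi[["intercept"]] + sum(phi[names(x)] * x)
        p <- if (phi_form == "as_printed") 1 - exp(-exp(eta) * T_k)
             else exp(-exp(eta) * T_k)
        total <- total + log(if (e == 1) p else 1 - p)
      } else {
        eta <- gamma[["intercept"]] + sum(gamma[names(x)] * x) +
          gamma[["distance"]] * dist_by_occ[i, k]
        p <- 1 - exp(-exp(eta) * T_k)
        if (types[k + 1] == "presence_only") {
          if (!is.na(e) && e == 1) total <- total + log(p)
          else if (policy == "absent") total <- total + log(1 - p)
        } else {
          if (is.na(e)) next
          total <- total + log(if (e == 1) p else 1 - p)
        }
      }
    }
  }
  total
}

# textbook split-chain potential scale reduction factor
oracle_rhat <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  half <- floor(n / 2)
  chains <- list()
  for (j in seq_len(m)) {
    chains[[2 * j - 1]] <- mat[seq_len(half), j]
    chains[[2 * j]] <- mat[(n - half + 1):n, j]
  }
  M <- length(chains)
  mns <- vapply(chains, mean, numeric(1))
  vs <- vapply(chains, stats::var, numeric(1))
  W <- mean(vs)
  B <- half / (M - 1) * sum((mns - mean(mns))^2)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# landscape whose per-occasion covariate layers are the supplied
# (already standardized) matrices, for direct likelihood checks
toy_landscape <- function(X_by_occasion, years) {
  n <- nrow(X_by_occasion[[1]])
  covs <- colnames(X_by_occasion[[1]])
  mats <- lapply(covs, function(nm) {
    m <- vapply(X_by_occasion, function(X) X[, nm], numeric(n))
    matrix(m, n, length(years))
  })
  names(mats) <- covs
  landscape(seq_len(n), x_km = seq_len(n) * 5, y_km = rep(0, n),
            covariates = mats, years = years)
}

# random tiny likelihood instance (<= 4 cells, <= 3 occasions)
random_loglik_instance <- function(seed) {
  set.seed(seed)
  n <- sample(1:4, 1)
  K <- sample(2:3, 1)
  years <- cumsum(c(2000, sample(5:25, K - 1, replace = TRUE)))
  p <- sample(1:3, 1)
  covs <- paste0("c", seq_len(p))
  types <- c(rep("presence_absence", K - 1),
             if (stats::runif(1) < 0.5) "presence_only" else "presence_absence")
  status <- matrix(NA_real_, n, K)
  status[, 1] <- stats::rbinom(n, 1, 0.5)
  for (k in 2:K) {
    if (types[k] == "presence_only") {
      # only newly present cells may be reported present
      status[, k] <- ifelse(status[, k - 1] %in% 1,
                            sample(c(0, NA), n, replace = TRUE),
                            stats::rbinom(n, 1, 0.5))
    } else {
      status[, k] <- sample(c(0, 1, NA), n, replace = TRUE)
    }
  }
  # keep every hazard h = exp(eta) * T inside [~0.003, ~11] so the
  # oracle's direct products (p, then log(1 - p)) are themselves
  # accurate to well below the 1e-10 comparison tolerance
  X_by_interval <- lapply(seq_len(K), function(k) {
    matrix(stats::runif(n * p, -1, 1), n, p, dimnames = list(NULL, covs))
  })
  dist_by_occ <- matrix(stats::runif(n * K, -1, 1), n, K)
  T_max <- max(diff(years))
  phi <- stats::setNames(c(log(stats::runif(1, 0.02, 1.5) / T_max),
                           stats::runif(p, -0.5, 0.5)),
                         c("intercept", covs))
  gamma <- stats::setNames(c(log(stats::runif(1, 0.02, 1.5) / T_max),
                             stats::runif(p + 1, -0.5, 0.5)),
                           c("intercept", covs, "distance"))
  policy <- sample(c("absent", "missing"), 1)
  list(n = n, K = K, years = years, types = types, status = status,
       X = X_by_interval, dist = dist_by_occ,
       coeffs = coefficient_set(phi, gamma), policy = policy)
}

# lag-1 spatial autocorrelation of a field stored x-fastest on a grid
lag1_cor <- function(v, n_x, n_y) {
  m <- matrix(v, n_x, n_y)
  stats::cor(as.vector(m[-n_x, ]), as.vector(m[-1, ]))
}

# small landscape with smooth-ish random covariates on the natural scale
small_landscape <- function(n_x, n_y, seed, years = c(1978, 2003, 2014)) {
  design <- simulation_design(n_x = n_x, n_y = n_y, seed = seed,
                              years = years)
  generate_covariates(design)
}
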