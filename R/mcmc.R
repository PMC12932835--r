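#' MCMC configuration
#'
#' Settings for the adaptive Metropolis-within-Gibbs sampler. The
#' default is a desk-scale protocol (3 chains, 2,000 burn-in + 4,000
#' sampling, thinning 2) suitable for simulation studies; the
#' `"survey"` preset is the heavy survey-scale protocol (burn-in 50,000,
#' 200,000 sampling steps, thinning 15).
#'
#' @param n_chains number of chains (>= 2 so R-hat is defined).
#' @param burn_in adaptation/warm-up iterations discarded per chain.
#' @param sampling post-burn-in iterations per chain.
#' @param thin thinning stride (retained draws = floor(sampling / thin)).
#' @param prior_sd prior standard deviation of every coefficient; the
#'   default `sqrt(1000)` is the vague Normal(0, variance 1000) prior.
#' @param impute_sd_max upper bound of the Uniform(0, max) hyperprior on
#'   the latent-imputation standard deviation.
#' @param rhat_threshold convergence gate (> 1).
#' @param adapt_interval proposal scales are re-tuned every this many
#'   burn-in iterations (adaptation is frozen after burn-in).
#' @param seed master seed; chain c runs on a seed derived from it.
#' @param preset `NULL` or `"survey"`.
#' @return object of class `rc_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, burn_in = 2000, sampling = 4000,
                        thin = 2, prior_sd = sqrt(1000),
                        impute_sd_max = 100, rhat_threshold = 1.1,
                        adapt_interval = 50, seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "survey")
    burn_in <- 50000; sampling <- 200000; thin <- 15
  }
  if (n_chains < 2) stop("need >= 2 chains for the R-hat diagnostic")
  if (burn_in < 0 || thin < 1 || sampling < thin)
    stop("invalid burn_in / sampling / thin settings")
  if (rhat_threshold <= 1) stop("rhat_threshold must exceed 1")
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 sampling = as.integer(sampling), thin = as.integer(thin),
                 prior_sd = prior_sd, impute_sd_max = impute_sd_max,
                 rhat_threshold = rhat_threshold,
                 adapt_interval = as.integer(adapt_interval),
                 seed = as.integer(seed)),
            class = "rc_mcmc_config")
}

# Bernoulli log-likelihood of one component given precomputed eta.
comp_loglik <- function(eta, y1, T, type, phi_form) {
  if (!length(eta)) return(0)
  if (type == "phi") {
    sum(phi_logp(eta[y1], T[y1], phi_form)) +
      sum(phi_log1mp(eta[!y1], T[!y1], phi_form))
  } else {
    sum(cloglog_logp(eta[y1], T[y1])) +
      sum(cloglog_log1mp(eta[!y1], T[!y1]))
  }
}

# Enumerate latent (missing) covariate entries from the stacked blocks.
# One latent per underlying landscape entry: static covariates are
# shared across intervals, time-varying ones are per occasion.
latent_layout <- function(blocks, landscape, covariates, years) {
  static <- covariates[!vapply(landscape$covariates[covariates],
                               is.matrix, logical(1))]
  pos <- list()
  for (comp in c("phi", "gamma")) {
    X <- blocks[[comp]]$X
    if (is.null(X) || !anyNA(X)) next
    na_idx <- which(is.na(X), arr.ind = TRUE)
    for (q in seq_len(nrow(na_idx))) {
      r <- as.integer(na_idx[q, 1]); cl <- as.integer(na_idx[q, 2])
      nm <- colnames(X)[cl]
      cell <- blocks[[comp]]$cell[r]
      yr <- years[blocks[[comp]]$interval[r]]
      key <- if (nm %in% static) paste(nm, cell, sep = ":")
             else paste(nm, cell, yr, sep = ":")
      if (is.null(pos[[key]]))
        pos[[key]] <- list(cov = nm, at = list())
      pos[[key]]$at[[length(pos[[key]]$at) + 1L]] <-
        c(comp = comp, row = r, col = cl)
    }
  }
  pos
}

# One adaptive Metropolis-within-Gibbs chain. `data` carries the
# intercept-augmented design matrices and outcomes; latent covariate
# entries (NA in the designs) are sampled with a Normal(0, sigma^2)
# prior on the standardized scale, sigma ~ Uniform(0, impute_sd_max).
mwg_chain <- function(data, config, chain_seed, phi_form, record_every) {
  set.seed(chain_seed)
  pphi <- ncol(data$Mphi); pgam <- ncol(data$Mgam)
  bphi <- numeric(pphi); bgam <- numeric(pgam)
  latents <- data$latents
  lat_v <- stats::setNames(numeric(length(latents)), names(latents))
  sig_groups <- unique(vapply(latents, `[[`, "", "cov"))
  sigma <- stats::setNames(rep(1, length(sig_groups)), sig_groups)

  Mphi <- data$Mphi; Mgam <- data$Mgam
  # fill latent entries with their initial value (0 = observed mean)
  for (l in latents) for (a in l$at) {
    if (a[["comp"]] == "phi") Mphi[as.integer(a[["row"]]), as.integer(a[["col"]])] <- 0
    else Mgam[as.integer(a[["row"]]), as.integer(a[["col"]])] <- 0
  }
  eta_phi <- drop(Mphi %*% bphi)
  eta_gam <- drop(Mgam %*% bgam)
  ll_phi <- comp_loglik(eta_phi, data$yphi1, data$Tphi, "phi", phi_form)
  ll_gam <- comp_loglik(eta_gam, data$ygam1, data$Tgam, "gamma", phi_form)
  if (!is.finite(ll_phi + ll_gam))
    stop("non-finite likelihood at initialization (all coefficients 0)")

  prior_sd <- config$prior_sd
  n_coef <- pphi + pgam
  scales <- rep(0.2, n_coef)
  lat_scales <- stats::setNames(rep(0.5, length(sig_groups)), sig_groups)
  sig_scales <- stats::setNames(rep(0.5, length(sig_groups)), sig_groups)
  acc <- numeric(n_coef); lat_acc <- lat_n <- stats::setNames(
    numeric(length(sig_groups)), sig_groups)
  sig_acc <- stats::setNames(numeric(length(sig_groups)), sig_groups)
  acc_total <- numeric(n_coef); prop_total <- 0

  n_iter <- config$burn_in + config$sampling
  n_ret <- config$sampling %/% config$thin
  out <- matrix(NA_real_, n_ret, n_coef + length(sig_groups))
  ret <- 0L

  # per-component adaptive-covariance block proposals: running moments
  # collected during burn-in, proposal covariance frozen afterwards
  blk <- list(
    phi = list(d = pphi, mu = numeric(pphi), S = matrix(0, pphi, pphi),
               n = 0, U = NULL, lsc = 0, acc = 0, cnt = 0),
    gamma = list(d = pgam, mu = numeric(pgam), S = matrix(0, pgam, pgam),
                 n = 0, U = NULL, lsc = 0, acc = 0, cnt = 0))
  blk_refresh <- function(bk) {
    cv <- bk$S / (bk$n - 1) + diag(1e-8, bk$d)
    U <- tryCatch(chol(cv), error = function(e) NULL)
    if (!is.null(U)) bk$U <- U * (2.38 / sqrt(bk$d))
    if (bk$cnt > 0) {
      bk$lsc <- max(min(bk$lsc + (bk$acc / bk$cnt - 0.25), 5), -5)
      bk$acc <- 0; bk$cnt <- 0
    }
    bk
  }

  for (iter in seq_len(n_iter)) {
    adapting <- iter <= config$burn_in
    # --- phi coefficients ---
    for (j in seq_len(pphi)) {
      if (!length(eta_phi)) break
      step <- stats::rnorm(1, 0, scales[j])
      eta_new <- eta_phi + step * Mphi[, j]
      ll_new <- comp_loglik(eta_new, data$yphi1, data$Tphi, "phi", phi_form)
      lr <- ll_new - ll_phi +
        stats::dnorm(bphi[j] + step, 0, prior_sd, log = TRUE) -
        stats::dnorm(bphi[j], 0, prior_sd, log = TRUE)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        bphi[j] <- bphi[j] + step; eta_phi <- eta_new; ll_phi <- ll_new
        acc[j] <- acc[j] + 1
      }
    }
    # --- gamma coefficients ---
    for (j in seq_len(pgam)) {
      if (!length(eta_gam)) break
      jj <- pphi + j
      step <- stats::rnorm(1, 0, scales[jj])
      eta_new <- eta_gam + step * Mgam[, j]
      ll_new <- comp_loglik(eta_new, data$ygam1, data$Tgam, "gamma", phi_form)
      lr <- ll_new - ll_gam +
        stats::dnorm(bgam[j] + step, 0, prior_sd, log = TRUE) -
        stats::dnorm(bgam[j], 0, prior_sd, log = TRUE)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        bgam[j] <- bgam[j] + step; eta_gam <- eta_new; ll_gam <- ll_new
        acc[jj] <- acc[jj] + 1
      }
    }
    # prior-only update when a component has no data rows
    if (!length(eta_phi)) bphi <- stats::rnorm(pphi, 0, prior_sd)
    if (!length(eta_gam)) bgam <- stats::rnorm(pgam, 0, prior_sd)

    # --- full-block multivariate proposals (one per component) ---
    if (length(eta_phi) && !is.null(blk$phi$U)) {
      step <- exp(blk$phi$lsc) * drop(stats::rnorm(pphi) %*% blk$phi$U)
      b_new <- bphi + step
      eta_new <- drop(Mphi %*% b_new)
      ll_new <- comp_loglik(eta_new, data$yphi1, data$Tphi, "phi", phi_form)
      lr <- ll_new - ll_phi +
        sum(stats::dnorm(b_new, 0, prior_sd, log = TRUE)) -
        sum(stats::dnorm(bphi, 0, prior_sd, log = TRUE))
      blk$phi$cnt <- blk$phi$cnt + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        bphi <- b_new; eta_phi <- eta_new; ll_phi <- ll_new
        blk$phi$acc <- blk$phi$acc + 1
      }
    }
    if (length(eta_gam) && !is.null(blk$gamma$U)) {
      step <- exp(blk$gamma$lsc) * drop(stats::rnorm(pgam) %*% blk$gamma$U)
      b_new <- bgam + step
      eta_new <- drop(Mgam %*% b_new)
      ll_new <- comp_loglik(eta_new, data$ygam1, data$Tgam, "gamma", phi_form)
      lr <- ll_new - ll_gam +
        sum(stats::dnorm(b_new, 0, prior_sd, log = TRUE)) -
        sum(stats::dnorm(bgam, 0, prior_sd, log = TRUE))
      blk$gamma$cnt <- blk$gamma$cnt + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        bgam <- b_new; eta_gam <- eta_new; ll_gam <- ll_new
        blk$gamma$acc <- blk$gamma$acc + 1
      }
    }
    if (adapting) {
      for (cm in c("phi", "gamma")) {
        b_cur <- if (cm == "phi") bphi else bgam
        bk <- blk[[cm]]
        bk$n <- bk$n + 1
        delta <- b_cur - bk$mu
        bk$mu <- bk$mu + delta / bk$n
        bk$S <- bk$S + outer(delta, b_cur - bk$mu)
        blk[[cm]] <- bk
      }
    }

    # --- latent covariate entries ---
    for (k in seq_along(latents)) {
      l <- latents[[k]]
      s <- sigma[l$cov]
      dv <- stats::rnorm(1, 0, lat_scales[l$cov])
      v_old <- lat_v[k]; v_new <- v_old + dv
      d_ll <- 0
      upd <- list()
      for (a in l$at) {
        r <- as.integer(a[["row"]]); cl <- as.integer(a[["col"]])
        if (a[["comp"]] == "phi") {
          de <- bphi[cl] * dv
          e_new <- eta_phi[r] + de
          d_ll <- d_ll +
            comp_loglik(e_new, data$yphi1[r], data$Tphi[r], "phi", phi_form) -
            comp_loglik(eta_phi[r], data$yphi1[r], data$Tphi[r], "phi", phi_form)
        } else {
          de <- bgam[cl] * dv
          e_new <- eta_gam[r] + de
          d_ll <- d_ll +
            comp_loglik(e_new, data$ygam1[r], data$Tgam[r], "gamma", phi_form) -
            comp_loglik(eta_gam[r], data$ygam1[r], data$Tgam[r], "gamma", phi_form)
        }
        upd[[length(upd) + 1L]] <- list(a = a, e_new = e_new)
      }
      lr <- d_ll + stats::dnorm(v_new, 0, s, log = TRUE) -
        stats::dnorm(v_old, 0, s, log = TRUE)
      lat_n[l$cov] <- lat_n[l$cov] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        lat_v[k] <- v_new
        for (u in upd) {
          r <- as.integer(u$a[["row"]]); cl <- as.integer(u$a[["col"]])
          if (u$a[["comp"]] == "phi") {
            Mphi[r, cl] <- v_new; eta_phi[r] <- u$e_new
          } else {
            Mgam[r, cl] <- v_new; eta_gam[r] <- u$e_new
          }
        }
        ll_phi <- comp_loglik(eta_phi, data$yphi1, data$Tphi, "phi", phi_form)
        ll_gam <- comp_loglik(eta_gam, data$ygam1, data$Tgam, "gamma", phi_form)
        lat_acc[l$cov] <- lat_acc[l$cov] + 1
      }
    }
    # --- imputation sd hyperparameters (log-scale random walk) ---
    for (g in sig_groups) {
      s_old <- sigma[g]
      s_new <- s_old * exp(stats::rnorm(1, 0, sig_scales[g]))
      if (s_new > 0 && s_new < config$impute_sd_max) {
        vals <- lat_v[vapply(latents, function(l) l$cov == g, logical(1))]
        lr <- sum(stats::dnorm(vals, 0, s_new, log = TRUE)) -
          sum(stats::dnorm(vals, 0, s_old, log = TRUE)) +
          log(s_new) - log(s_old)  # Jacobian of the log-scale proposal
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          sigma[g] <- s_new
          sig_acc[g] <- sig_acc[g] + 1
        }
      }
    }

    # --- proposal-scale adaptation, frozen after burn-in ---
    if (adapting && iter %% config$adapt_interval == 0) {
      for (cm in c("phi", "gamma"))
        if (blk[[cm]]$n > 2 * blk[[cm]]$d)
          blk[[cm]] <- blk_refresh(blk[[cm]])
      rate <- acc / config$adapt_interval
      scales <- pmin(pmax(scales * exp(rate - 0.3), 1e-4), 1e4)
      acc_total <- acc_total + acc
      prop_total <- prop_total + config$adapt_interval
      acc[] <- 0
      if (length(sig_groups)) {
        lrate <- ifelse(lat_n > 0, lat_acc / lat_n, 0.3)
        lat_scales <- pmin(pmax(lat_scales * exp(lrate - 0.3), 1e-4), 1e4)
        srate <- sig_acc / config$adapt_interval
        sig_scales <- pmin(pmax(sig_scales * exp(srate - 0.3), 1e-4), 1e4)
        lat_acc[] <- 0; lat_n[] <- 0; sig_acc[] <- 0
      }
    }

    if (!adapting && (iter - config$burn_in) %% config$thin == 0) {
      ret <- ret + 1L
      out[ret, ] <- c(bphi, bgam, sigma)
    }
  }
  list(draws = out,
       accept = if (prop_total > 0) acc_total / prop_total else NA_real_)
}

#' Fit the dynamic occupancy model by Metropolis-within-Gibbs MCMC
#'
#' Samples the persistence and colonization coefficients under vague
#' Normal(0, variance `prior_sd^2`) priors with adaptive random-walk
#' Metropolis updates (one coordinate at a time, adaptation frozen after
#' burn-in so the stationary distribution is preserved). Missing
#' covariate entries are sampled as latent values with a
#' Normal(observed mean, sigma^2) prior on the standardized scale (so
#' mean 0) and sigma drawn under a Uniform(0, `impute_sd_max`)
#' hyperprior. Fully reproducible from the config seed.
#'
#' Covariates are standardized internally with the first-occasion stats
#' (distance layer included) unless `stats` is supplied.
#'
#' @param survey an `rc_survey` (first occasion fully observed).
#' @param landscape an `rc_landscape` on the natural covariate scale.
#' @param config an `rc_mcmc_config`.
#' @param covariates environmental covariates to include (default: all
#'   landscape covariates, e.g. after [spearman_screen()]).
#' @param policy presence-only policy (see [log_likelihood()]).
#' @param phi_form persistence parameterization (see [log_likelihood()]).
#' @param stats optional precomputed standardization stats.
#' @return object of class `rc_draws`: retained draws indexed
#'   iteration x chain x parameter, with the config, seed, stats and
#'   per-chain acceptance rates attached.
#' @export
fit_mcmc <- function(survey, landscape, config = mcmc_config(),
                     covariates = names(landscape$covariates),
                     policy = c("absent", "missing"),
                     phi_form = c("as_printed", "survival"),
                     stats = NULL) {
  policy <- match.arg(policy)
  phi_form <- match.arg(phi_form)
  for (nm in covariates)
    if (all(is.na(landscape$covariates[[nm]])))
      stop("covariate '", nm, "' is entirely missing")

  dist_raw <- survey_distance_layers(survey, landscape)
  if (is.null(stats))
    stats <- fit_stats(landscape, survey$years[1], dist_raw[, 1],
                       covariates)
  ls_std <- standardize_landscape(landscape, stats, covariates)
  i <- match("distance", stats$covariate)
  dist_std <- (dist_raw - stats$mean[i]) / stats$sd[i]

  blocks <- transition_blocks(survey, ls_std, dist_std, covariates, policy)
  if (!length(blocks$phi$y))
    warning("no observed present-start transitions: persistence ",
            "coefficients are informed by the prior only")
  if (!length(blocks$gamma$y))
    warning("no observed absent-start transitions: colonization ",
            "coefficients are informed by the prior only")

  aug <- function(b, p) if (is.null(b$X)) matrix(0, 0, p) else cbind(1, b$X)
  data <- list(
    Mphi = aug(blocks$phi, length(covariates) + 1L),
    yphi1 = blocks$phi$y == 1, Tphi = blocks$phi$T,
    Mgam = aug(blocks$gamma, length(covariates) + 2L),
    ygam1 = blocks$gamma$y == 1,
    Tgam = blocks$gamma$T,
    latents = latent_layout(blocks, landscape, covariates, survey$years))
  # latent column indices refer to the intercept-augmented matrices
  data$latents <- lapply(data$latents, function(l) {
    l$at <- lapply(l$at, function(a) {
      a[["col"]] <- as.integer(a[["col"]]) + 1L; a })
    l
  })

  pphi <- length(covariates) + 1L
  pgam <- length(covariates) + 2L
  sig_groups <- unique(vapply(data$latents, `[[`, "", "cov"))
  par_names <- c(paste0("phi_", c("intercept", covariates)),
                 paste0("gamma_", c("intercept", covariates, "distance")),
                 if (length(sig_groups)) paste0("sigma_", sig_groups))

  n_ret <- config$sampling %/% config$thin
  draws <- array(NA_real_, c(n_ret, config$n_chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  accept <- matrix(NA_real_, config$n_chains, pphi + pgam)
  for (c in seq_len(config$n_chains)) {
    res <- mwg_chain(data, config, stage_seed(config$seed, paste0("chain_", c)),
                     phi_form, config$thin)
    draws[, c, ] <- res$draws
    accept[c, ] <- res$accept
  }
  structure(list(draws = draws, parameters = par_names,
                 covariates = covariates, distance_name = "distance",
                 config = config, seed = config$seed, stats = stats,
                 policy = policy, phi_form = phi_form,
                 accept_rates = accept,
                 data_digest = sprintf("%d cells x %d occasions; %d presences",
                                       nrow(survey$status),
                                       length(survey$years),
                                       sum(survey$status == 1, na.rm = TRUE))),
            class = "rc_draws")
}

#' @export
print.rc_draws <- function(x, ...) {
  cat("rc_draws:", dim(x$draws)[1], "retained draws x", dim(x$draws)[2],
      "chains x", dim(x$draws)[3], "parameters\n")
  cat("  data:", x$data_digest, "\n")
  invisible(x)
}

#' Pool retained draws into one matrix
#' @param draws an `rc_draws`.
#' @return matrix (iterations * chains) x parameters.
#' @export
draws_matrix <- function(draws) {
  a <- draws$draws
  m <- matrix(a, dim(a)[1] * dim(a)[2], dim(a)[3])
  colnames(m) <- draws$parameters
  m
}

#' Wrap a fixed coefficient set as degenerate posterior draws
#'
#' Utility for forecasting or prediction from known coefficients (e.g.
#' synthetic truth): every draw equals the supplied set.
#'
#' @param coeffs an `rc_coefficients`.
#' @param stats standardization stats the coefficients live on.
#' @param n_draws number of (identical) draws.
#' @param policy,phi_form carried through to consumers.
#' @return an `rc_draws` with one chain of identical draws.
#' @export
posterior_from_coefficients <- function(coeffs, stats, n_draws = 1,
                                        policy = "absent",
                                        phi_form = "as_printed") {
  covs <- coef_covariates(coeffs)
  par_names <- c(paste0("phi_", c("intercept", covs)),
                 paste0("gamma_", c("intercept", covs, "distance")))
  row <- c(coeffs$phi[["intercept"]], coeffs$phi[covs],
           coeffs$gamma[["intercept"]], coeffs$gamma[covs],
           coeffs$gamma[[coeffs$distance_name]])
  a <- array(rep(row, each = n_draws), c(n_draws, 1, length(par_names)),
             dimnames = list(NULL, NULL, par_names))
  structure(list(draws = a, parameters = par_names, covariates = covs,
                 distance_name = "distance", config = NULL, seed = NA,
                 stats = stats, policy = policy, phi_form = phi_form,
                 accept_rates = NULL, data_digest = "fixed coefficients"),
            class = "rc_draws")
}

#' Split-chain Gelman-Rubin potential scale reduction factor
#'
#' Each chain's retained draws are split in half; R-hat compares
#' between- and within-sequence variance across the resulting
#' sequences. A parameter with zero within-chain variance has an
#' undefined statistic and is reported as NA with `converged = NA`.
#'
#' @param draws an `rc_draws`, or a 3-d array (iteration x chain x
#'   parameter), or a matrix (iteration x chain) for a single parameter.
#' @param threshold convergence bound (default 1.1).
#' @return data frame: parameter, rhat, converged.
#' @export
compute_rhat <- function(draws, threshold = 1.1) {
  a <- if (inherits(draws, "rc_draws")) draws$draws else draws
  if (is.matrix(a)) a <- array(a, c(dim(a), 1))
  if (dim(a)[2] < 2) stop("R-hat needs >= 2 chains")
  if (dim(a)[1] < 10) stop("R-hat needs >= 10 retained draws per chain")
  pnames <- dimnames(a)[[3]]
  if (is.null(pnames)) pnames <- paste0("par", seq_len(dim(a)[3]))
  half <- dim(a)[1] %/% 2
  rhat <- vapply(seq_len(dim(a)[3]), function(p) {
    seqs <- do.call(cbind, lapply(seq_len(dim(a)[2]), function(ch)
      cbind(a[seq_len(half), ch, p],
            a[(dim(a)[1] - half + 1):dim(a)[1], ch, p])))
    W <- mean(apply(seqs, 2, stats::var))
    B <- half * stats::var(colMeans(seqs))
    if (!is.finite(W) || W == 0) return(NA_real_)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  data.frame(parameter = pnames, rhat = rhat,
             converged = ifelse(is.na(rhat), NA, rhat < threshold))
}

#' Posterior summary table
#'
#' Per-parameter median and central 95% credible interval over the
#' pooled chains, with a significance flag set when the interval
#' excludes zero (how the study reads its coefficient tables).
#'
#' @param draws an `rc_draws`.
#' @param prob central interval mass (default 0.95).
#' @return data frame: parameter, median, lo, hi, significant.
#' @export
summarize_posterior <- function(draws, prob = 0.95) {
  m <- draws_matrix(draws)
  if (!nrow(m)) stop("no retained draws to summarize")
  alpha <- (1 - prob) / 2
  q <- apply(m, 2, stats::quantile, probs = c(alpha, 0.5, 1 - alpha),
             names = FALSE)
  data.frame(parameter = colnames(m), median = q[2, ], lo = q[1, ],
             hi = q[3, ], significant = q[1, ] > 0 | q[3, ] < 0,
             row.names = NULL)
}
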