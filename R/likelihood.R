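#' Build per-interval transition blocks
#'
#' Internal workhorse shared by the likelihood, the sampler and the
#' in-sample prediction check. For each inter-occasion interval it
#' collects, separately for the persistence (start-present) and
#' colonization (start-absent) submodels, the evaluable cells, their
#' 0/1 end outcomes, the interval length (the hazard offset, raw years)
#' and the standardized covariate rows at the interval start.
#'
#' Presence-only end occasions contribute colonization information only:
#' start-absent cells reported present are colonizations; unreported
#' start-absent cells are non-colonizations under `policy = "absent"`
#' and are dropped under `policy = "missing"`; start-present cells carry
#' no persistence information and are excluded.
#'
#' @param survey an `rc_survey` whose first occasion is fully observed
#'   presence/absence.
#' @param landscape an `rc_landscape` with standardized covariates.
#' @param distances `n_cells x n_occasions` matrix of standardized
#'   distance-to-nearest-occupied layers (column k = layer at occasion k).
#' @param covariates character vector of environmental covariate names.
#' @param policy `"absent"` or `"missing"`: meaning of unreported cells
#'   in a presence-only occasion.
#' @param distance_name column name given to the distance covariate.
#' @return list with elements `phi` and `gamma`, each a list of
#'   `X` (covariate matrix), `y` (0/1 outcome), `T` (offset per row),
#'   `cell` and `interval` indices.
#' @keywords internal
transition_blocks <- function(survey, landscape, distances, covariates,
                              policy = c("absent", "missing"),
                              distance_name = "distance") {
  policy <- match.arg(policy)
  K <- length(survey$years)
  if (survey$occasion_type[1] != "presence_absence" ||
      anyNA(survey$status[, 1]))
    stop("the first occasion must be a fully observed presence/absence round")
  if (nrow(survey$status) != n_cells(landscape))
    stop("survey and landscape cell counts differ")

  acc <- list(phi = list(), gamma = list())
  for (k in seq_len(K - 1)) {
    start <- survey$status[, k]
    end <- survey$status[, k + 1]
    type_end <- survey$occasion_type[k + 1]
    T_k <- survey$years[k + 1] - survey$years[k]
    if (T_k <= 0) stop("non-positive survey interval")
    X <- covariate_matrix(landscape, survey$years[k], covariates)

    if (type_end == "presence_only") {
      bad <- which(!is.na(start) & start == 1 & !is.na(end) & end == 1)
      if (length(bad))
        stop("data inconsistency: cell(s) ",
             paste(utils::head(survey$cell_id[bad], 5), collapse = ", "),
             " reported newly present at a presence-only occasion ",
             "but already present at the interval start")
      idx_g <- which(!is.na(start) & start == 0)
      y_g <- as.integer(!is.na(end[idx_g]) & end[idx_g] == 1)
      if (policy == "missing") {
        keep <- y_g == 1
        idx_g <- idx_g[keep]; y_g <- y_g[keep]
      }
      idx_p <- integer(); y_p <- integer()
    } else {
      idx_p <- which(!is.na(start) & start == 1 & !is.na(end))
      y_p <- end[idx_p]
      idx_g <- which(!is.na(start) & start == 0 & !is.na(end))
      y_g <- end[idx_g]
    }

    if (length(idx_p))
      acc$phi[[length(acc$phi) + 1L]] <- list(
        X = X[idx_p, , drop = FALSE], y = y_p,
        T = rep(T_k, length(idx_p)), cell = idx_p,
        interval = rep(k, length(idx_p)))
    if (length(idx_g)) {
      Xg <- cbind(X[idx_g, , drop = FALSE], distances[idx_g, k])
      colnames(Xg) <- c(covariates, distance_name)
      acc$gamma[[length(acc$gamma) + 1L]] <- list(
        X = Xg, y = y_g, T = rep(T_k, length(idx_g)), cell = idx_g,
        interval = rep(k, length(idx_g)))
    }
  }
  bind <- function(parts) {
    if (!length(parts))
      return(list(X = NULL, y = integer(), T = numeric(),
                  cell = integer(), interval = integer()))
    list(X = do.call(rbind, lapply(parts, `[[`, "X")),
         y = unlist(lapply(parts, `[[`, "y")),
         T = unlist(lapply(parts, `[[`, "T")),
         cell = unlist(lapply(parts, `[[`, "cell")),
         interval = unlist(lapply(parts, `[[`, "interval")))
  }
  list(phi = bind(acc$phi), gamma = bind(acc$gamma))
}

# Bernoulli log-likelihood of one block under one coefficient vector.
# eta may be supplied precomputed (the sampler's incremental path).
block_loglik <- function(block, coeffs, phi_form = "as_printed",
                         component = c("gamma", "phi"), eta = NULL) {
  component <- match.arg(component)
  if (!length(block$y)) return(0)
  if (is.null(eta)) eta <- linear_predictor(coeffs, block$X)
  if (component == "phi") {
    lp <- phi_logp(eta, block$T, phi_form)
    lq <- phi_log1mp(eta, block$T, phi_form)
  } else {
    lp <- cloglog_logp(eta, block$T)
    lq <- cloglog_log1mp(eta, block$T)
  }
  sum(ifelse(block$y == 1, lp, lq))
}

#' Observed-data log-likelihood of the dynamic occupancy model
#'
#' Sums, over cells and inter-occasion intervals, the log-probability of
#' each observed transition: start-present cells contribute
#' `log(phi)` / `log(1 - phi)`, start-absent cells `log(gamma)` /
#' `log(1 - gamma)`. A final presence-only occasion informs colonization
#' only (see [transition_blocks()]). A structurally impossible
#' observation yields `-Inf` with a diagnostic attribute rather than an
#' error.
#'
#' @param survey an `rc_survey` (first occasion fully observed).
#' @param landscape an `rc_landscape` carrying *standardized* covariates.
#' @param coeffs an `rc_coefficients` on the same standardized scale.
#' @param distances `n_cells x n_occasions` matrix of standardized
#'   interval-start distance layers.
#' @param policy presence-only policy, `"absent"` (unreported cells are
#'   treated as still absent; the default) or `"missing"` (unreported
#'   cells carry no information).
#' @param phi_form `"as_printed"` (persistence is the cloglog interval
#'   probability, as the model is stated) or `"survival"` (persistence is
#'   the survivor function of a constant extinction hazard).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(survey, landscape, coeffs, distances,
                           policy = c("absent", "missing"),
                           phi_form = c("as_printed", "survival")) {
  policy <- match.arg(policy)
  phi_form <- match.arg(phi_form)
  covs <- coef_covariates(coeffs)
  blocks <- transition_blocks(survey, landscape, distances, covs, policy,
                              coeffs$distance_name)
  if ((length(blocks$phi$y) && anyNA(blocks$phi$X)) ||
      (length(blocks$gamma$y) && anyNA(blocks$gamma$X)))
    stop("covariate matrix contains missing values; impute before ",
         "evaluating the likelihood (fit_mcmc handles this as latent values)")
  ll <- block_loglik(blocks$phi, coeffs$phi, phi_form, "phi") +
    block_loglik(blocks$gamma, coeffs$gamma, phi_form, "gamma")
  if (!is.finite(ll) && !is.nan(ll))
    attr(ll, "diagnostic") <- "structurally impossible observation (log 0)"
  ll
}
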