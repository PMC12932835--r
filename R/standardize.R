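#' Standardize covariates (z-score), or apply previously computed stats
#'
#' All explanatory variables — including the nearest-occupied distance —
#' are centred and scaled before entering the model, so coefficient
#' magnitudes are directly comparable. Stats are computed on the
#' non-missing fitting entries with the n-1 standard-deviation
#' denominator. On the forecast path the fitting-period stats are reused
#' unchanged (`stats` supplied), never re-estimated.
#'
#' @param values numeric matrix or data frame, one column per covariate.
#' @param stats optional stats object returned by a previous call; when
#'   supplied, the same affine transform is applied.
#' @return list with `values` (standardized matrix, NA preserved) and
#'   `stats` (data frame with columns covariate, mean, sd).
#' @export
standardize <- function(values, stats = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("covariate columns must be named")
  if (is.null(stats)) {
    mu <- apply(values, 2, mean, na.rm = TRUE)
    sdv <- apply(values, 2, stats::sd, na.rm = TRUE)
    zero <- which(!is.finite(sdv) | sdv == 0)
    if (length(zero))
      stop("cannot standardize zero-variance covariate(s): ",
           paste(colnames(values)[zero], collapse = ", "))
    stats <- data.frame(covariate = colnames(values), mean = mu, sd = sdv,
                        row.names = NULL)
  } else {
    i <- match(colnames(values), stats$covariate)
    if (anyNA(i))
      stop("no standardization stats for covariate(s): ",
           paste(colnames(values)[is.na(i)], collapse = ", "))
    mu <- stats$mean[i]
    sdv <- stats$sd[i]
  }
  out <- sweep(sweep(values, 2, mu, "-"), 2, sdv, "/")
  list(values = out, stats = stats)
}

#' Invert a standardization (for reporting on the natural scale)
#' @param values standardized matrix with covariate column names.
#' @param stats stats object from [standardize()].
#' @return matrix on the original covariate scale.
#' @export
unstandardize <- function(values, stats) {
  values <- as.matrix(values)
  i <- match(colnames(values), stats$covariate)
  if (anyNA(i))
    stop("no standardization stats for covariate(s): ",
         paste(colnames(values)[is.na(i)], collapse = ", "))
  sweep(sweep(values, 2, stats$sd[i], "*"), 2, stats$mean[i], "+")
}

#' Collinearity screen by Spearman rank correlation
#'
#' Computes pairwise Spearman rho on complete cases; for every pair with
#' `|rho| >= threshold` the member later in the priority order is
#' dropped, and every flagged pair is reported with its rho.
#'
#' @param table numeric matrix or data frame of candidate covariates.
#' @param threshold correlation bound in (0, 1]; default 0.6.
#' @param priority character vector giving the preference order; defaults
#'   to column order.
#' @return list with `retained` (names kept, in priority order),
#'   `dropped` (data frame: drop, keep, rho), and `rho` (full matrix).
#' @export
spearman_screen <- function(table, threshold = 0.6,
                            priority = colnames(as.matrix(table))) {
  table <- as.matrix(table)
  if (ncol(table) < 2) stop("need at least two covariates to screen")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (!setequal(priority, colnames(table)))
    stop("priority must be a permutation of the covariate names")
  cc <- stats::complete.cases(table)
  if (sum(cc) < 3)
    stop("fewer than 3 complete cases: rank correlation is meaningless")
  rho <- stats::cor(table[cc, , drop = FALSE], method = "spearman")
  drop <- character()
  rep_drop <- rep_keep <- character()
  rep_rho <- numeric()
  for (a in seq_along(priority)) {
    for (b in seq_along(priority)) {
      if (b <= a) next
      r <- rho[priority[a], priority[b]]
      if (is.finite(r) && abs(r) >= threshold) {
        rep_drop <- c(rep_drop, priority[b])
        rep_keep <- c(rep_keep, priority[a])
        rep_rho <- c(rep_rho, r)
        drop <- union(drop, priority[b])
      }
    }
  }
  list(retained = setdiff(priority, drop),
       dropped = data.frame(drop = rep_drop, keep = rep_keep, rho = rep_rho),
       rho = rho)
}
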