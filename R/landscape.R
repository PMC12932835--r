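#' Gridded landscape object
#'
#' A landscape holds the cell lattice (integer ids plus projected planar
#' centroid coordinates in kilometres) and the per-cell covariate layers.
#' Covariates are either static (one value per cell, e.g. elevation) or
#' time-varying (one value per cell per occasion year, e.g. human
#' population). Missing entries are stored as `NA` and are never dropped;
#' downstream code decides how to treat them (standardization skips them,
#' the sampler imputes them as latent values).
#'
#' @param cell_id integer vector of unique cell identifiers.
#' @param x_km,y_km numeric centroid coordinates in kilometres (projected
#'   planar; distances between centroids are Euclidean).
#' @param covariates named list. Static covariates are numeric vectors of
#'   length `n_cells`; time-varying covariates are `n_cells x n_years`
#'   matrices with year column names matching `years`.
#' @param years integer vector of occasion years the time-varying layers
#'   are indexed by (strictly increasing).
#' @return an object of class `rc_landscape`.
#' @export
landscape <- function(cell_id, x_km, y_km, covariates = list(), years = integer()) {
  cell_id <- as.integer(cell_id)
  n <- length(cell_id)
  if (anyDuplicated(cell_id)) {
    dup <- cell_id[duplicated(cell_id)][1L]
    stop("duplicate cell_id: ", dup)
  }
  if (length(x_km) != n || length(y_km) != n)
    stop("coordinate vectors must match cell_id length")
  if (!all(is.finite(x_km)) || !all(is.finite(y_km)))
    stop("cell centroids must be finite")
  if (anyDuplicated(cbind(x_km, y_km)))
    stop("two cells share a centroid")
  years <- as.integer(years)
  if (length(years) && any(diff(years) <= 0))
    stop("years must be strictly increasing")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.matrix(v)) {
      if (nrow(v) != n)
        stop("covariate '", nm, "' has ", nrow(v), " rows; expected ", n)
      if (ncol(v) != length(years))
        stop("time-varying covariate '", nm, "' must have one column per year")
      colnames(v) <- as.character(years)
      covariates[[nm]] <- v
    } else {
      if (length(v) != n)
        stop("covariate '", nm, "' has length ", length(v), "; expected ", n)
    }
    if (!is.numeric(v)) stop("covariate '", nm, "' is not numeric")
  }
  ord <- order(cell_id)
  structure(list(
    cell_id = cell_id[ord],
    x_km = as.numeric(x_km)[ord],
    y_km = as.numeric(y_km)[ord],
    years = years,
    covariates = lapply(covariates, function(v)
      if (is.matrix(v)) v[ord, , drop = FALSE] else v[ord])
  ), class = "rc_landscape")
}

#' @export
print.rc_landscape <- function(x, ...) {
  tv <- names(x$covariates)[vapply(x$covariates, is.matrix, logical(1))]
  st <- setdiff(names(x$covariates), tv)
  cat("rc_landscape:", length(x$cell_id), "cells\n")
  cat("  years:", paste(x$years, collapse = ", "), "\n")
  cat("  static covariates:", paste(st, collapse = ", "), "\n")
  cat("  time-varying covariates:", paste(tv, collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells in a landscape
#' @param landscape an `rc_landscape`.
#' @return integer cell count.
#' @export
n_cells <- function(landscape) length(landscape$cell_id)

#' Extract the covariate matrix for one occasion year
#'
#' Static covariates are recycled across years. Columns are ordered as
#' requested, which is how the coefficient names are bound to covariate
#' identities throughout the package.
#'
#' @param landscape an `rc_landscape`.
#' @param year occasion year; must be one of `landscape$years` for any
#'   time-varying covariate requested.
#' @param covariates character vector of covariate names; defaults to all.
#' @return numeric matrix, `n_cells x length(covariates)`.
#' @export
covariate_matrix <- function(landscape, year, covariates = names(landscape$covariates)) {
  missing_cov <- setdiff(covariates, names(landscape$covariates))
  if (length(missing_cov))
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  cols <- lapply(covariates, function(nm) {
    v <- landscape$covariates[[nm]]
    if (is.matrix(v)) {
      j <- match(as.character(year), colnames(v))
      if (is.na(j))
        stop("covariate '", nm, "' has no layer for year ", year)
      v[, j]
    } else v
  })
  out <- do.call(cbind, cols)
  colnames(out) <- covariates
  out
}

#' Read a landscape from CSV
#'
#' Expected columns: `cell_id`, `x_km`, `y_km`, then one column per
#' covariate layer. Time-varying layers are named `<covariate>_<year>`
#' (e.g. `human_pop_1978`); static layers carry the bare covariate name
#' (e.g. `elevation`). Blank entries become `NA` and are kept, not
#' dropped. Columns not matching the declared schema are ignored with a
#' warning.
#'
#' @param path CSV file path.
#' @param covariates character vector of covariate names to load.
#' @return an `rc_landscape` with rows ordered by `cell_id`.
#' @export
load_landscape <- function(path, covariates) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  for (req in c("cell_id", "x_km", "y_km"))
    if (!req %in% names(df)) stop("missing required column: ", req)
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id: ", df$cell_id[duplicated(df$cell_id)][1L])

  other <- setdiff(names(df), c("cell_id", "x_km", "y_km"))
  parsed <- lapply(other, function(col) {
    m <- regmatches(col, regexec("^(.*)_([0-9]{4})$", col))[[1]]
    if (length(m) == 3 && m[2] %in% covariates)
      list(col = col, cov = m[2], year = as.integer(m[3]))
    else if (col %in% covariates)
      list(col = col, cov = col, year = NA_integer_)
    else NULL
  })
  known <- !vapply(parsed, is.null, logical(1))
  if (any(!known))
    warning("ignoring unrecognised column(s): ",
            paste(other[!known], collapse = ", "))
  parsed <- parsed[known]

  for (p in parsed) {
    v <- df[[p$col]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric value in column '", p$col, "', row ", bad)
    }
  }

  years <- sort(unique(unlist(lapply(parsed, function(p) p$year))))
  years <- years[!is.na(years)]
  covs <- list()
  for (nm in covariates) {
    mine <- Filter(function(p) p$cov == nm, parsed)
    if (!length(mine)) stop("no column found for covariate '", nm, "'")
    if (all(is.na(vapply(mine, function(p) p$year, integer(1))))) {
      covs[[nm]] <- as.numeric(df[[mine[[1]]$col]])
    } else {
      m <- matrix(NA_real_, nrow(df), length(years),
                  dimnames = list(NULL, as.character(years)))
      for (p in mine) m[, as.character(p$year)] <- as.numeric(df[[p$col]])
      covs[[nm]] <- m
    }
  }
  landscape(df$cell_id, df$x_km, df$y_km, covs, years)
}

#' Write a landscape to CSV (inverse of [load_landscape()])
#' @param landscape an `rc_landscape`.
#' @param path output CSV path.
#' @export
write_landscape_csv <- function(landscape, path) {
  df <- data.frame(cell_id = landscape$cell_id,
                   x_km = landscape$x_km, y_km = landscape$y_km)
  for (nm in names(landscape$covariates)) {
    v <- landscape$covariates[[nm]]
    if (is.matrix(v)) {
      for (yr in colnames(v)) df[[paste0(nm, "_", yr)]] <- v[, yr]
    } else df[[nm]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a per-cell layer as GeoJSON square polygons
#'
#' Writes each cell as a square of the given edge centred on its centroid,
#' with the supplied values attached as a `value` property. Coordinates are
#' the landscape's planar kilometre coordinates (no CRS is implied).
#'
#' @param landscape an `rc_landscape`.
#' @param values numeric vector, one value per cell.
#' @param path output file path.
#' @param edge_km cell edge length in km (default 5).
#' @export
write_cell_geojson <- function(landscape, values, path, edge_km = 5) {
  stopifnot(length(values) == n_cells(landscape))
  h <- edge_km / 2
  feats <- lapply(seq_along(landscape$cell_id), function(i) {
    x <- landscape$x_km[i]; y <- landscape$y_km[i]
    ring <- list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
                 c(x - h, y + h), c(x - h, y - h))
    list(type = "Feature",
         properties = list(cell_id = landscape$cell_id[i], value = values[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
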