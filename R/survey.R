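#' Occupancy survey object
#'
#' Per-cell presence/absence status over an ordered set of survey
#' occasions. Each occasion is either `presence_absence` (0/1/NA per
#' cell) or `presence_only` (a round that recorded only newly detected
#' presences — the meaning of cells not reported as present is governed
#' by a policy declared at analysis time, not stored here).
#'
#' @param years strictly increasing integer vector of survey years.
#' @param status `n_cells x n_occasions` matrix with entries 0, 1 or NA.
#' @param occasion_type character vector, one of `"presence_absence"` or
#'   `"presence_only"` per occasion.
#' @param cell_id optional integer cell identifiers (default `1:n`).
#' @return an object of class `rc_survey`.
#' @export
occupancy_survey <- function(years, status, occasion_type, cell_id = NULL) {
  years <- as.integer(years)
  if (length(years) < 2) stop("at least two survey occasions are required")
  if (any(diff(years) <= 0)) stop("survey years must be strictly increasing")
  status <- as.matrix(status)
  if (ncol(status) != length(years))
    stop("status must have one column per occasion")
  if (!all(status %in% c(0, 1) | is.na(status)))
    stop("status entries must be 0, 1 or NA")
  occasion_type <- match.arg(occasion_type,
                             c("presence_absence", "presence_only"),
                             several.ok = TRUE)
  if (length(occasion_type) != length(years))
    stop("occasion_type must have one entry per occasion")
  if (is.null(cell_id)) cell_id <- seq_len(nrow(status))
  colnames(status) <- as.character(years)
  structure(list(years = years, status = status,
                 occasion_type = occasion_type,
                 cell_id = as.integer(cell_id)),
            class = "rc_survey")
}

#' @export
print.rc_survey <- function(x, ...) {
  cat("rc_survey:", nrow(x$status), "cells x", length(x$years), "occasions\n")
  for (k in seq_along(x$years)) {
    s <- x$status[, k]
    cat(sprintf("  %d (%s): %d present, %d absent, %d NA\n",
                x$years[k], x$occasion_type[k],
                sum(s == 1, na.rm = TRUE), sum(s == 0, na.rm = TRUE),
                sum(is.na(s))))
  }
  invisible(x)
}

#' Read an occupancy survey from long-format CSV
#'
#' Expected columns: `cell_id`, `year`, `status` (0, 1 or empty/NA).
#' Occasion types are supplied by the caller (they are run metadata, not
#' part of the data file).
#'
#' @param path CSV file path.
#' @param occasion_type character vector, one entry per distinct year in
#'   the file (ordered by year).
#' @return an `rc_survey` with cells ordered by `cell_id`.
#' @export
load_occupancy <- function(path, occasion_type) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  for (req in c("cell_id", "year", "status"))
    if (!req %in% names(df)) stop("missing required column: ", req)
  years <- sort(unique(df$year))
  cells <- sort(unique(df$cell_id))
  status <- matrix(NA_real_, length(cells), length(years))
  i <- match(df$cell_id, cells)
  j <- match(df$year, years)
  status[cbind(i, j)] <- df$status
  occupancy_survey(years, status, occasion_type, cell_id = cells)
}

#' Write an occupancy survey to long-format CSV
#' @param survey an `rc_survey`.
#' @param path output CSV path.
#' @export
write_survey_csv <- function(survey, path) {
  df <- data.frame(
    cell_id = rep(survey$cell_id, times = length(survey$years)),
    year = rep(survey$years, each = nrow(survey$status)),
    status = as.vector(survey$status))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
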