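#' Distance to the nearest occupied cell
#'
#' For every occupied cell the distance is 0 km; for every unoccupied
#' cell it is the Euclidean distance between centroids to the closest
#' occupied cell. This layer is the model's stand-in for dispersal
#' limitation / spatial autocorrelation, and it is recomputed from the
#' current occupancy pattern at every transition.
#'
#' @param landscape an `rc_landscape`.
#' @param occupied binary (0/1 or logical) vector, one entry per cell.
#' @return numeric vector of non-negative finite distances in km.
#' @export
nearest_occupied_distance <- function(landscape, occupied) {
  n <- n_cells(landscape)
  if (length(occupied) != n)
    stop("occupied must have one entry per cell (", n, ")")
  occ <- which(as.logical(occupied))
  if (!length(occ))
    stop("no occupied cell: nearest-occupied distance is undefined ",
         "(the empty-range case must be handled by the caller)")
  d <- numeric(n)
  un <- which(!as.logical(occupied))
  if (!length(un)) return(d)
  xo <- landscape$x_km[occ]
  yo <- landscape$y_km[occ]
  # block over unoccupied cells to bound the n x m distance matrix
  block <- 2048L
  for (s in seq(1L, length(un), by = block)) {
    idx <- un[s:min(s + block - 1L, length(un))]
    dx <- outer(landscape$x_km[idx], xo, "-")
    dy <- outer(landscape$y_km[idx], yo, "-")
    d2 <- dx * dx + dy * dy
    d[idx] <- sqrt(do.call(pmin, c(split(d2, col(d2)), list(na.rm = FALSE))))
  }
  d
}
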