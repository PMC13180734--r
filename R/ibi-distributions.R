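# Inter-breath-interval probability densities conditioned on PMA or brain
# age gap: per-recording histograms at 0.1-s resolution (IBIs > 50 s
# removed, unit area), combined across recordings by a Gaussian-weighted
# per-bin weighted median.

IBI_BIN_S <- 0.1
IBI_MAX_S <- 50
GAUSS_FWHM_DAYS <- 13
GAUSS_CUTOFF_DAYS <- 14

#' Per-recording IBI probability density
#'
#' Frequency distribution of the recording's IBIs on [0, 50) s at 0.1-s
#' resolution, with IBIs longer than 50 s removed, normalised so the area
#' under the curve equals 1.
#'
#' @param intervals IBIs in seconds (an [extract_ibis()] object is also
#'   accepted).
#' @return A list of class `recording_density` with `bin_left` (s),
#'   `density` (1/s), `n_ibis`.
#' @export
recording_density <- function(intervals) {
  if (inherits(intervals, "ibi_series")) intervals <- intervals$intervals
  kept <- intervals[intervals <= IBI_MAX_S]
  abort_if(length(kept) == 0, "no IBIs of 50 s or shorter")
  edges <- seq(0, IBI_MAX_S, by = IBI_BIN_S)
  idx <- pmin(floor(kept / IBI_BIN_S) + 1L, length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  dens <- counts / (length(kept) * IBI_BIN_S)
  structure(list(bin_left = edges[-length(edges)], density = dens,
                 n_ibis = length(kept)),
            class = "recording_density")
}

#' Gaussian distance weights over developmental age
#'
#' Gaussian window with a full width at half maximum of 13 days
#' (sigma = 13 / (2 sqrt(2 ln 2))); weights for distances of more than 14
#' days are set to 0.
#'
#' @param distance_days absolute age difference(s), days.
#' @return Weight(s) in [0, 1].
#' @export
gaussian_weights <- function(distance_days) {
  sigma <- GAUSS_FWHM_DAYS / (2 * sqrt(2 * log(2)))
  w <- exp(-distance_days^2 / (2 * sigma^2))
  w[abs(distance_days) > GAUSS_CUTOFF_DAYS] <- 0
  w
}

# Lower weighted median: smallest value whose cumulative normalised weight
# reaches 0.5.
weighted_median <- function(values, weights) {
  o <- order(values)
  cw <- cumsum(weights[o]) / sum(weights)
  values[o][which(cw >= 0.5)[1]]
}

#' Combine recording densities by per-bin weighted median
#'
#' The conditional density at a grid point is, per 0.1-s bin, the weighted
#' median of the recording densities with the given weights, renormalised
#' afterwards to unit area (weighted medians of unit-area densities need not
#' themselves integrate to 1).
#'
#' @param densities a list of [recording_density()] objects, or a matrix
#'   (bins x recordings).
#' @param weights one non-negative weight per recording.
#' @return A list of class `recording_density`, or NULL when every weight is
#'   0 (empty grid point).
#' @export
weighted_median_density <- function(densities, weights) {
  if (is.list(densities) && !is.matrix(densities)) {
    bin_left <- densities[[1]]$bin_left
    mat <- vapply(densities, function(d) d$density,
                  numeric(length(bin_left)))
  } else {
    mat <- as.matrix(densities)
    bin_left <- seq(0, by = IBI_BIN_S, length.out = nrow(mat))
  }
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  abort_if(length(weights) != ncol(mat),
           "need one weight per recording")
  abort_if(any(weights < 0), "weights must be non-negative")
  if (sum(weights) == 0) return(NULL)
  pos <- weights > 0
  mat <- mat[, pos, drop = FALSE]
  weights <- weights[pos]
  med <- apply(mat, 1, weighted_median, weights = weights)
  area <- sum(med) * IBI_BIN_S
  if (area > 0) med <- med / area
  structure(list(bin_left = bin_left, density = med, n_ibis = NA_integer_),
            class = "recording_density")
}

#' Build the density grid over PMA or brain age gap
#'
#' Conditional IBI densities (and cumulative distributions) on a 1-day grid
#' over 31-36 weeks PMA or -3 to 3 weeks gap. At each grid point, recording
#' weights follow [gaussian_weights()] applied to the age distance in days;
#' grid points with no recording within 14 days are left empty.
#'
#' @param densities list of [recording_density()] objects.
#' @param axis_values one conditioning value (PMA or gap, weeks) per
#'   recording.
#' @param axis `"pma"` or `"gap"` (sets the default grid range).
#' @param grid optional explicit grid (weeks).
#' @return A list of class `density_grid`: `axis`, `grid` (weeks),
#'   `density` (bins x grid points; NA columns where empty), `cumulative`,
#'   `bin_left`, `weights` (recordings x grid points).
#' @export
build_density_grid <- function(densities, axis_values,
                               axis = c("pma", "gap"), grid = NULL) {
  axis <- match.arg(axis)
  abort_if(length(densities) != length(axis_values),
           "need one axis value per recording")
  if (is.null(grid)) {
    grid <- if (axis == "pma") {
      seq(31, 36, by = 1 / 7)
    } else {
      seq(-3, 3, by = 1 / 7)
    }
  }
  bin_left <- densities[[1]]$bin_left
  wmat <- vapply(grid, function(g) {
    gaussian_weights(abs(axis_values - g) * 7)
  }, numeric(length(densities)))
  if (is.null(dim(wmat))) wmat <- matrix(wmat, nrow = length(densities))
  abort_if(all(colSums(wmat) == 0),
           "no recording lies within 14 days of any grid point")
  dens <- matrix(NA_real_, length(bin_left), length(grid))
  for (j in seq_along(grid)) {
    wm <- weighted_median_density(densities, wmat[, j])
    if (!is.null(wm)) dens[, j] <- wm$density
  }
  cum <- apply(dens, 2, function(d) {
    if (all(is.na(d))) d else cumsum(d) * IBI_BIN_S
  })
  structure(list(axis = axis, grid = grid, density = dens, cumulative = cum,
                 bin_left = bin_left, weights = wmat),
            class = "density_grid")
}

#' Export a density grid as a long-format data frame
#'
#' @param dg a [build_density_grid()] object.
#' @return Data frame with columns `axis_value`, `bin_left_s`, `density`,
#'   `cumulative`, suitable for (log-log) plotting.
#' @export
density_grid_long <- function(dg) {
  data.frame(
    axis_value = rep(dg$grid, each = length(dg$bin_left)),
    bin_left_s = rep(dg$bin_left, length(dg$grid)),
    density = as.numeric(dg$density),
    cumulative = as.numeric(dg$cumulative)
  )
}
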