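# Fractality descriptors.
#
# Box-counting (Hausdorff) dimension of the centroid set over a dyadic box
# ladder from 10 um up to at most 1100 um, plus Higuchi fractal dimensions
# of the horizontal and vertical projection series (per-pixel-column and
# per-pixel-row cell counts) and their average. A plane-filling pattern
# approaches dimension 2, collinear cells 1.

#' Box-counting (Hausdorff) dimension of a cell pattern
#'
#' Boxes of side 10, 20, 40, ..., capped at 1100 um, grid anchored at the
#' frame origin; the dimension is the least-squares slope of log N(s)
#' against log(1/s).
#'
#' @param pattern `cell_pattern`.
#' @param min_box_um,max_box_um box ladder limits.
#' @return estimated dimension; 0 with a warning when `n_cells < 2`.
#' @export
boxcount_dimension <- function(pattern, min_box_um = 10, max_box_um = 1100) {
  if (pattern$n_cells < 2L) {
    warning("fewer than 2 cells; box-counting dimension set to 0")
    return(0)
  }
  sizes <- min_box_um * 2^(0:floor(log2(max_box_um / min_box_um)))
  N <- vapply(sizes, function(s) {
    bx <- floor(pattern$x_um / s)
    by <- floor(pattern$y_um / s)
    length(unique(bx * 2^26 + by))
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, log(1 / sizes)), log(N))
  unname(fit$coefficients[2])
}

#' Projection series of a cell pattern
#'
#' Horizontal series: number of cells in each pixel column (a function of
#' x); vertical series: number of cells in each pixel row.
#'
#' @param pattern `cell_pattern`.
#' @param resolution_um_per_px bin width in micrometres (the export pixel
#'   size).
#' @return list with numeric vectors `horizontal` and `vertical`.
#' @export
higuchi_projections <- function(pattern, resolution_um_per_px = 0.454) {
  res <- resolution_um_per_px
  ncols <- max(1L, ceiling(pattern$frame_um[1] / res))
  nrows <- max(1L, ceiling(pattern$frame_um[2] / res))
  h <- tabulate(pmin(pmax(floor(pattern$x_um / res) + 1L, 1L), ncols), ncols)
  v <- tabulate(pmin(pmax(floor(pattern$y_um / res) + 1L, 1L), nrows), nrows)
  list(horizontal = as.numeric(h), vertical = as.numeric(v))
}

#' Higuchi fractal dimension of a 1D series
#'
#' Classical Higuchi estimator: for each interval k = 1..k_max and offset m,
#' the normalised curve length
#' `L_m(k) = ((N-1) / (floor((N-m)/k) k^2)) * sum |X(m+ik) - X(m+(i-1)k)|`
#' is averaged over offsets; the dimension is the slope of log L(k) against
#' log(1/k). Smooth series give 1, white noise 2.
#'
#' @param series numeric vector, length at least `2 * k_max`.
#' @param k_max largest subsampling interval (default 8).
#' @return estimated dimension; 1 for a series with zero total variation.
#' @export
higuchi_fd <- function(series, k_max = 8) {
  N <- length(series)
  if (N < 2 * k_max) stop("series too short for k_max = ", k_max)
  if (all(series == series[1])) return(1)
  Lk <- numeric(k_max)
  for (k in 1:k_max) {
    Lm <- numeric(k)
    for (m in 1:k) {
      idx <- seq(m, N, by = k)
      ni <- length(idx) - 1L
      if (ni < 1L) { Lm[m] <- NA; next }
      Lm[m] <- sum(abs(diff(series[idx]))) * (N - 1) / (ni * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  keep <- Lk > 0
  if (sum(keep) < 2) return(1)
  fit <- stats::lm.fit(cbind(1, log(1 / (1:k_max))[keep]), log(Lk[keep]))
  unname(fit$coefficients[2])
}

#' The 4-feature fractality block
#'
#' Box-counting dimension plus horizontal/vertical Higuchi dimensions of
#' the projection series and their average, named `frac_boxcount`,
#' `frac_higuchi_h`, `frac_higuchi_v`, `frac_higuchi_avg`.
#'
#' @param pattern `cell_pattern`.
#' @param resolution_um_per_px projection bin width.
#' @param k_max Higuchi interval cap; shrunk automatically for very short
#'   series.
#' @return named numeric vector of length 4.
#' @export
fractal_block <- function(pattern, resolution_um_per_px = 0.454, k_max = 8) {
  bc <- suppressWarnings(boxcount_dimension(pattern))
  pr <- higuchi_projections(pattern, resolution_um_per_px)
  fd1 <- function(s) {
    km <- min(k_max, floor(length(s) / 2))
    if (km < 2 || pattern$n_cells == 0L) return(0)
    higuchi_fd(s, km)
  }
  h <- fd1(pr$horizontal)
  v <- fd1(pr$vertical)
  c(frac_boxcount = bc, frac_higuchi_h = h, frac_higuchi_v = v,
    frac_higuchi_avg = (h + v) / 2)
}
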