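# Stochastic-geometry descriptors: process intensity, Ripley's K and the
# variance-stabilised L function over radii 5..50 um in steps of 2.5.
#
# K is estimated for a stationary process with translation edge correction
# on the bounding rectangle of the observation window:
#   K(r) = |W| / n^2 * sum_{i != j} 1(d_ij <= r) * e_ij,
#   e_ij = (a b) / ((a - |dx|)(b - |dy|)).
# |W| is the outlined-mask area when a mask exists, the rectangle area
# otherwise. Under complete spatial randomness K(r) = pi r^2 and L(r) = r.

PP_RADII_UM <- seq(5, 50, by = 2.5)

#' Process intensity (cells per mm^2)
#'
#' @param pattern `cell_pattern`.
#' @return `n_cells / included_area_mm2`.
#' @export
pattern_intensity <- function(pattern) {
  if (is.na(pattern$area_mm2) || pattern$area_mm2 <= 0)
    stop("window area must be positive")
  pattern$n_cells / pattern$area_mm2
}

#' Ripley's K and L functions
#'
#' @param pattern `cell_pattern`.
#' @param radii_um evaluation radii in micrometres (default 5 to 50 by 2.5,
#'   19 values).
#' @return list of class `k_estimate` with `radii_um`, `K` (um^2), `L` (um)
#'   and `intensity_per_mm2`. Patterns with fewer than 2 cells give zero
#'   curves with a warning.
#' @export
ripley_k <- function(pattern, radii_um = PP_RADII_UM) {
  n <- pattern$n_cells
  intensity <- if (pattern$area_mm2 > 0) n / pattern$area_mm2 else 0
  if (n < 2L) {
    warning("fewer than 2 cells; K undefined, returning zeros")
    return(structure(list(radii_um = radii_um, K = numeric(length(radii_um)),
                          L = numeric(length(radii_um)),
                          intensity_per_mm2 = intensity),
                     class = "k_estimate"))
  }
  a <- pattern$frame_um[1]; b <- pattern$frame_um[2]
  W <- pattern$area_mm2 * 1e6   # um^2
  sums <- cpp_ripley_sums(pattern$x_um, pattern$y_um, radii_um, a, b)
  K <- W / n^2 * sums
  structure(list(radii_um = radii_um, K = K, L = sqrt(K / pi),
                 intensity_per_mm2 = intensity),
            class = "k_estimate")
}

#' The 39-feature stochastic-geometry block
#'
#' 1 intensity + 19 K values + 19 L values, named `pp_intensity`,
#' `pp_K_{r}`, `pp_L_{r}`.
#'
#' @param pattern `cell_pattern`.
#' @return named numeric vector of length 39.
#' @export
pp_feature_block <- function(pattern) {
  est <- suppressWarnings(ripley_k(pattern))
  out <- c(pattern_intensity(pattern), est$K, est$L)
  names(out) <- c("pp_intensity",
                  sprintf("pp_K_%g", est$radii_um),
                  sprintf("pp_L_%g", est$radii_um))
  out
}
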