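# Windowed Shannon-entropy descriptors.
#
# The frame is partitioned into adjacent square windows anchored at the
# frame origin. Only windows lying completely inside the observation window
# (the non-black, outlined region) contribute. Each window's cell count n is
# an occurrence of the event "a window contains n cells"; the entropy of the
# empirical count distribution, H = -sum_e p_e log2 p_e, is the feature.
# Low entropy indicates a repetitive, organised arrangement.

ENTROPY_SIDES_UM <- c(20, 40, 80, 160, 320, 640)

# qualifying windows: indices (i, j), 0-based, of grid cells fully inside
# the window mask (or the frame rectangle when no mask is present).
.qualifying_windows <- function(pattern, side_um) {
  fx <- pattern$frame_um[1]; fy <- pattern$frame_um[2]
  nx <- floor(fx / side_um + 1e-9); ny <- floor(fy / side_um + 1e-9)
  if (nx < 1 || ny < 1) return(NULL)
  ok <- matrix(TRUE, ny, nx)
  w <- pattern$window
  if (!is.null(w)) {
    res <- w$resolution_um_per_px
    m <- w$mask
    cs <- rbind(0, apply(m * 1, 2, cumsum))
    cs <- cbind(0, t(apply(t(cs), 2, cumsum)))
    for (j in seq_len(nx)) for (i in seq_len(ny)) {
      r1 <- floor((i - 1) * side_um / res) + 1
      r2 <- ceiling(i * side_um / res)
      c1 <- floor((j - 1) * side_um / res) + 1
      c2 <- ceiling(j * side_um / res)
      if (r2 > nrow(m) || c2 > ncol(m)) { ok[i, j] <- FALSE; next }
      npx <- (r2 - r1 + 1) * (c2 - c1 + 1)
      s <- cs[r2 + 1, c2 + 1] - cs[r2 + 1, c1] - cs[r1, c2 + 1] + cs[r1, c1]
      ok[i, j] <- (s == npx)
    }
  }
  ok
}

#' Shannon entropy of per-window cell counts
#'
#' @param pattern `cell_pattern`.
#' @param side_um window side in micrometres.
#' @param base logarithm base (2 = bits, the default).
#' @return entropy `H >= 0`; 0 with a warning when no window qualifies.
#' @export
window_entropy <- function(pattern, side_um, base = 2) {
  ok <- .qualifying_windows(pattern, side_um)
  if (is.null(ok) || !any(ok)) {
    warning("no window of side ", side_um, " um fully inside the region")
    return(0)
  }
  ny <- nrow(ok); nx <- ncol(ok)
  counts <- matrix(0L, ny, nx)
  if (pattern$n_cells > 0) {
    ix <- floor(pattern$x_um / side_um) + 1
    iy <- floor(pattern$y_um / side_um) + 1
    inside <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    if (any(inside)) {
      t <- table(factor(iy[inside], levels = 1:ny),
                 factor(ix[inside], levels = 1:nx))
      counts <- matrix(as.integer(t), ny, nx)
    }
  }
  obs <- counts[ok]
  p <- as.numeric(table(obs)) / length(obs)
  -sum(p * log(p, base = base))
}

#' The 6-feature information-theory block
#'
#' One windowed entropy per side in 20/40/80/160/320/640 um, named
#' `H_{side}um`.
#'
#' @param pattern `cell_pattern`.
#' @param sides_um window sides.
#' @param base logarithm base.
#' @return named numeric vector of length 6.
#' @export
entropy_block <- function(pattern, sides_um = ENTROPY_SIDES_UM, base = 2) {
  out <- vapply(sides_um, function(s)
    suppressWarnings(window_entropy(pattern, s, base)), numeric(1))
  names(out) <- sprintf("H_%gum", sides_um)
  out
}

#' Windowed skewness variant (not part of the 490-feature set)
#'
#' Skewness of the per-window count distribution over qualifying windows,
#' exposed for exploration alongside the entropy features.
#'
#' @inheritParams window_entropy
#' @export
window_count_skewness <- function(pattern, side_um) {
  ok <- .qualifying_windows(pattern, side_um)
  if (is.null(ok) || !any(ok)) return(0)
  ny <- nrow(ok); nx <- ncol(ok)
  counts <- matrix(0L, ny, nx)
  if (pattern$n_cells > 0) {
    ix <- floor(pattern$x_um / side_um) + 1
    iy <- floor(pattern$y_um / side_um) + 1
    inside <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    if (any(inside)) {
      t <- table(factor(iy[inside], levels = 1:ny),
                 factor(ix[inside], levels = 1:nx))
      counts <- matrix(as.integer(t), ny, nx)
    }
  }
  v <- as.numeric(counts[ok])
  m2 <- mean((v - mean(v))^2)
  if (m2 == 0) return(0)
  mean((v - mean(v))^3) / m2^1.5
}
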