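# Planar point-pattern container for detected Ki-67-positive nuclei.
#
# Coordinates are in micrometres in the rotated/cropped slide frame, with
# the origin at the frame's top-left corner, x growing rightwards and y
# downwards. The observation window is either the outlined-region mask (at
# pixel resolution) or, in its absence, the bounding rectangle
# [0, frame_um[1]] x [0, frame_um[2]].

#' Construct a cell pattern
#'
#' @param x_um,y_um centroid coordinates in micrometres.
#' @param frame_um numeric length-2, width and height of the enclosing frame
#'   in micrometres. Defaults to the tight bounding box of the points.
#' @param window optional `region_mask` describing the observation window at
#'   pixel resolution; when supplied its `included_area_mm2` is used as the
#'   window area.
#' @param area_mm2 window area override in mm^2 (ignored when `window` is
#'   given).
#' @return object of class `cell_pattern` with fields `n_cells` and
#'   `density_per_mm2`.
#' @export
cell_pattern <- function(x_um, y_um, frame_um = NULL, window = NULL,
                         area_mm2 = NULL) {
  stopifnot(length(x_um) == length(y_um))
  if (is.null(frame_um)) {
    frame_um <- if (length(x_um)) c(max(x_um), max(y_um)) else c(1, 1)
  }
  if (!is.null(window)) {
    stopifnot(inherits(window, "region_mask"))
    area_mm2 <- window$included_area_mm2
  } else if (is.null(area_mm2)) {
    area_mm2 <- prod(frame_um) / 1e6
  }
  if (length(x_um) && (any(x_um < -1e-9) || any(y_um < -1e-9) ||
                       any(x_um > frame_um[1] + 1e-9) ||
                       any(y_um > frame_um[2] + 1e-9)))
    warning("centroids outside the stated frame")
  n <- length(x_um)
  structure(list(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 frame_um = as.numeric(frame_um), window = window,
                 area_mm2 = area_mm2, n_cells = n,
                 density_per_mm2 = if (area_mm2 > 0) n / area_mm2 else NA_real_),
            class = "cell_pattern")
}

#' @export
print.cell_pattern <- function(x, ...) {
  cat(sprintf("cell_pattern: %d cells in %.3g x %.3g um frame (%.4g mm2, %.4g cells/mm2)\n",
              x$n_cells, x$frame_um[1], x$frame_um[2], x$area_mm2,
              x$density_per_mm2))
  invisible(x)
}

#' Write centroids as CSV (columns x_um, y_um)
#' @param pattern `cell_pattern`.
#' @param path output file.
#' @export
write_pattern_csv <- function(pattern, path) {
  write.csv(data.frame(x_um = pattern$x_um, y_um = pattern$y_um), path,
            row.names = FALSE)
  invisible(path)
}

#' Read centroids from CSV
#' @param path CSV with columns `x_um`, `y_um`.
#' @param frame_um,area_mm2 see [cell_pattern()].
#' @export
read_pattern_csv <- function(path, frame_um = NULL, area_mm2 = NULL) {
  d <- read.csv(path)
  stopifnot(all(c("x_um", "y_um") %in% names(d)))
  cell_pattern(d$x_um, d$y_um, frame_um = frame_um, area_mm2 = area_mm2)
}
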