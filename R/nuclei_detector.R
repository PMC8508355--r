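# Ki-67-positive nucleus detection.
#
# DAB chromogen stains positive nuclei brown; haematoxylin counterstains
# negative nuclei blue. The detector smooths the image (median then
# Gaussian), thresholds brown-shaded pixels on the RGB channels -- all bounds
# fixed except the upper blue bound, which is the one parameter that varies
# between images to absorb staining-intensity differences -- cleans the
# binary raster, splits touching nuclei on the distance transform, filters
# aggregates by physical size and emits one centroid per surviving nucleus.

#' Detection parameters
#'
#' Kernel sizes follow the export magnification: 5x5 px at 20x (0.454
#' um/px), 3x3 px at 10x. The fixed RGB bounds describe DAB brown
#' (red-dominant, R > G > B); they are deliberately loose because the
#' per-image blue bound does the discriminating work.
#'
#' @param magnification `"20x"` or `"10x"`.
#' @param median_kernel_px,gaussian_kernel_px odd kernel sides; default 5 at
#'   20x, 3 at 10x.
#' @param gaussian_sigma Gaussian standard deviation in pixels.
#' @param r_bounds,g_bounds lower/upper bounds on the red and green
#'   channels (0-255).
#' @param b_lower lower bound on blue.
#' @param blue_upper upper bound on blue, or `"auto"` for an Otsu split of
#'   the blue channel within pixels passing the fixed bounds.
#' @param box_blur_kernel_px box-blur side used during cleaning.
#' @param min_nucleus_area_um2,max_nucleus_area_um2 size filter in um^2.
#' @param watershed_min_sep_um minimum seed separation when splitting
#'   touching nuclei.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(magnification = "20x",
                             median_kernel_px = NULL,
                             gaussian_kernel_px = NULL,
                             gaussian_sigma = 0.5,
                             r_bounds = c(90, 240),
                             g_bounds = c(30, 190),
                             b_lower = 0,
                             blue_upper = "auto",
                             box_blur_kernel_px = NULL,
                             min_nucleus_area_um2 = 15,
                             max_nucleus_area_um2 = 250,
                             watershed_min_sep_um = 3) {
  k <- if (identical(magnification, "20x")) 5L else 3L
  if (is.null(median_kernel_px)) median_kernel_px <- k
  if (is.null(gaussian_kernel_px)) gaussian_kernel_px <- k
  if (is.null(box_blur_kernel_px)) box_blur_kernel_px <- k
  stopifnot(median_kernel_px %% 2 == 1, gaussian_kernel_px %% 2 == 1,
            box_blur_kernel_px %% 2 == 1,
            min_nucleus_area_um2 < max_nucleus_area_um2)
  if (is.numeric(blue_upper)) stopifnot(blue_upper >= 0, blue_upper <= 255)
  structure(list(magnification = magnification,
                 median_kernel_px = median_kernel_px,
                 gaussian_kernel_px = gaussian_kernel_px,
                 gaussian_sigma = gaussian_sigma,
                 r_bounds = r_bounds, g_bounds = g_bounds, b_lower = b_lower,
                 blue_upper = blue_upper,
                 box_blur_kernel_px = box_blur_kernel_px,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 max_nucleus_area_um2 = max_nucleus_area_um2,
                 watershed_min_sep_um = watershed_min_sep_um),
            class = "detection_params")
}

# separable convolution with replicate padding
.conv_sep <- function(m, kern) {
  h <- (length(kern) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  if (length(kern) > nr || length(kern) > nc) stop("kernel larger than image")
  padr <- rbind(m[rep(1L, h), , drop = FALSE], m, m[rep(nr, h), , drop = FALSE])
  out <- matrix(0, nr, nc)
  for (i in seq_along(kern))
    out <- out + kern[i] * padr[i:(i + nr - 1L), , drop = FALSE]
  padc <- cbind(out[, rep(1L, h), drop = FALSE], out, out[, rep(nc, h), drop = FALSE])
  res <- matrix(0, nr, nc)
  for (i in seq_along(kern))
    res <- res + kern[i] * padc[, i:(i + nc - 1L), drop = FALSE]
  res
}

.gauss_kernel <- function(k, sigma) {
  x <- seq(-(k - 1) / 2, (k - 1) / 2)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

#' Median-then-Gaussian smoothing of an RGB slide
#'
#' @param slide `annotated_slide`.
#' @param params `detection_params`.
#' @return smoothed `annotated_slide`.
#' @export
smooth_image <- function(slide, params = detection_params()) {
  px <- slide$pixels
  gk <- .gauss_kernel(params$gaussian_kernel_px, params$gaussian_sigma)
  for (k in 1:3) {
    ch <- cpp_median_filter(px[, , k], params$median_kernel_px)
    px[, , k] <- .conv_sep(ch, gk)
  }
  annotated_slide(px, slide$resolution_um_per_px, slide$magnification_tag)
}

# Otsu threshold of a 0-255 vector; returns the cut value (<= cut kept).
.otsu <- function(v) {
  if (length(v) < 2L || length(unique(v)) < 2L) return(255)
  h <- tabulate(pmin(pmax(floor(v), 0), 255) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L
}

#' Brown-pixel thresholding
#'
#' White where all fixed RGB bounds hold and blue does not exceed the
#' per-image upper bound, restricted to the inclusion mask.
#'
#' @param slide smoothed `annotated_slide`.
#' @param params `detection_params`.
#' @param mask optional `region_mask`.
#' @return logical matrix (TRUE = candidate brown pixel). The resolved blue
#'   upper bound is attached as attribute `blue_upper`.
#' @export
threshold_brown <- function(slide, params = detection_params(), mask = NULL) {
  r <- slide$pixels[, , 1]; g <- slide$pixels[, , 2]; b <- slide$pixels[, , 3]
  fixed <- r >= params$r_bounds[1] & r <= params$r_bounds[2] &
    g >= params$g_bounds[1] & g <= params$g_bounds[2] & b >= params$b_lower &
    r > g & g >= b          # brown ordering: DAB is red-dominant
  if (!is.null(mask)) fixed <- fixed & mask$mask
  bu <- params$blue_upper
  if (identical(bu, "auto")) bu <- .otsu(b[fixed])
  out <- fixed & b <= bu
  attr(out, "blue_upper") <- bu
  out
}

#' Clean a thresholded binary raster
#'
#' Box blur re-binarised at 0.5, removal of isolated white pixels (no white
#' 8-neighbour), then filling of enclosed black holes.
#'
#' @param binary logical matrix.
#' @param params `detection_params`.
#' @return logical matrix.
#' @export
clean_and_fill <- function(binary, params = detection_params()) {
  k <- params$box_blur_kernel_px
  h <- (k - 1L) / 2L
  nr <- nrow(binary); nc <- ncol(binary)
  pad <- binary[c(rep(1L, h), 1:nr, rep(nr, h)),
                c(rep(1L, h), 1:nc, rep(nc, h)), drop = FALSE] * 1
  cs <- rbind(0, apply(pad, 2, cumsum))
  cs <- cbind(0, t(apply(t(cs), 2, cumsum)))   # summed-area table, 1-padded
  sumk <- cs[(1:nr) + k, (1:nc) + k, drop = FALSE] -
    cs[(1:nr) + k, 1:nc, drop = FALSE] -
    cs[1:nr, (1:nc) + k, drop = FALSE] + cs[1:nr, 1:nc, drop = FALSE]
  b <- sumk / (k * k) >= 0.5
  # drop isolated white pixels (zero white 8-neighbours)
  nb <- matrix(0L, nr, nc)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs2 <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs2] <- m[rs - dr, cs2 - dc, drop = FALSE]
    out
  }
  bi <- b * 1L
  for (dr in -1:1) for (dc in -1:1) if (dr || dc) nb <- nb + shift(bi, dr, dc)
  b <- b & nb > 0L
  # fill enclosed black areas: black components not touching the border
  lab <- cpp_label_components(!b, 4L)
  border <- setdiff(unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc])), 0L)
  b | (!b & !(matrix(lab %in% border, nr, nc)))
}

#' Split touching nuclei and measure centroids
#'
#' Connected white blobs are split on the Euclidean distance transform:
#' local maxima separated by at least `watershed_min_sep_um` seed the split,
#' every blob pixel joins its nearest seed. Components with physical area
#' outside the nucleus-size bounds are discarded; each survivor contributes
#' its centroid, converted to micrometres.
#'
#' @param binary cleaned logical matrix.
#' @param params `detection_params`.
#' @param resolution_um_per_px micrometres per pixel.
#' @param window optional `region_mask` carried into the output pattern.
#' @return `cell_pattern` (possibly empty).
#' @export
split_and_measure <- function(binary, params = detection_params(),
                              resolution_um_per_px = 0.454, window = NULL) {
  res <- resolution_um_per_px
  comp <- cpp_label_components(binary, 8L)
  frame <- c(ncol(binary), nrow(binary)) * res
  if (max(comp) == 0L)
    return(cell_pattern(numeric(0), numeric(0), frame_um = frame,
                        window = window))
  edt <- sqrt(cpp_edt_sq(binary))
  seeds <- cpp_pick_seeds(edt, comp, params$watershed_min_sep_um / res, 1.0)
  lab <- cpp_split_by_seeds(comp, seeds)
  n <- max(lab)
  if (n == 0L)
    return(cell_pattern(numeric(0), numeric(0), frame_um = frame,
                        window = window))
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area_px <- tabulate(l, n)
  area_um2 <- area_px * res^2
  keep <- area_um2 >= params$min_nucleus_area_um2 &
    area_um2 <= params$max_nucleus_area_um2
  cx <- (tapply(cols, l, mean) - 0.5) * res
  cy <- (tapply(rows, l, mean) - 0.5) * res
  cell_pattern(as.numeric(cx[keep]), as.numeric(cy[keep]), frame_um = frame,
               window = window)
}

#' Full detection pipeline on an annotated slide
#'
#' Smoothing, brown thresholding, cleaning, splitting and size filtering, in
#' that order. When `mask` is `NULL` the whole frame is used.
#'
#' @param slide `annotated_slide` (already rotated/cropped if that
#'   normalisation is wanted).
#' @param mask optional `region_mask`.
#' @param params `detection_params`.
#' @return `cell_pattern`.
#' @export
detect_cells <- function(slide, mask = NULL, params = NULL) {
  if (is.null(params)) params <- detection_params(slide$magnification_tag)
  sm <- smooth_image(slide, params)
  bw <- threshold_brown(sm, params, mask)
  bw <- clean_and_fill(bw, params)
  split_and_measure(bw, params, slide$resolution_um_per_px, window = mask)
}
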