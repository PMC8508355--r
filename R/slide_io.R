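# Annotated-slide ingestion: outline-derived masks, orientation
# normalisation and framing.
#
# Slides arrive as RGB bitmap exports of whole-slide images with hand-drawn
# overlay contours: green delimits viable neoplastic tissue, red marks areas
# to exclude (necrosis, artefacts). The mask keeps exactly the pixels inside
# a green contour and outside every red one; contour pixels themselves are
# dropped because overlay colour would corrupt downstream colour
# thresholding.

#' Construct an annotated slide
#'
#' @param pixels numeric array `h x w x 3`, 8-bit channel values in 0..255.
#' @param resolution_um_per_px micrometres per pixel; 0.454 corresponds to a
#'   20x export and 0.908 to a 10x export.
#' @param magnification_tag `"20x"` or `"10x"`; inferred from the resolution
#'   when missing.
#' @return an object of class `annotated_slide`.
#' @export
annotated_slide <- function(pixels, resolution_um_per_px,
                            magnification_tag = NULL) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (any(dim(pixels)[1:2] == 0L)) stop("empty raster")
  if (!is.numeric(resolution_um_per_px) || resolution_um_per_px <= 0)
    stop("resolution_um_per_px must be a positive real")
  if (is.null(magnification_tag)) {
    magnification_tag <- if (abs(resolution_um_per_px - 0.454) <
                             abs(resolution_um_per_px - 0.908)) "20x" else "10x"
  }
  if (!resolution_um_per_px %in% c(0.454, 0.908))
    warning("non-standard resolution (expected 0.454 or 0.908 um/px)")
  structure(list(pixels = pixels,
                 resolution_um_per_px = resolution_um_per_px,
                 magnification_tag = magnification_tag),
            class = "annotated_slide")
}

#' Read an annotated slide from a PNG file
#'
#' @param path PNG file.
#' @inheritParams annotated_slide
#' @export
read_slide_png <- function(path, resolution_um_per_px) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  annotated_slide(round(px * 255), resolution_um_per_px)
}

#' Write a slide (or a mask) as PNG
#' @param x `annotated_slide` or `region_mask`.
#' @param path output file.
#' @export
write_slide_png <- function(x, path) {
  if (inherits(x, "annotated_slide")) {
    png::writePNG(x$pixels / 255, path)
  } else if (inherits(x, "region_mask")) {
    png::writePNG(x$mask * 1.0, path)
  } else stop("unsupported object")
  invisible(path)
}

#' Construct a region mask
#'
#' @param mask logical matrix aligned with the slide raster.
#' @param resolution_um_per_px micrometres per pixel.
#' @return object of class `region_mask` with `included_area_mm2` equal to
#'   the true-pixel count times the squared resolution, in mm^2.
#' @export
region_mask <- function(mask, resolution_um_per_px) {
  stopifnot(is.logical(mask), is.matrix(mask))
  structure(list(mask = mask,
                 resolution_um_per_px = resolution_um_per_px,
                 included_area_mm2 = sum(mask) * resolution_um_per_px^2 / 1e6),
            class = "region_mask")
}

# classify overlay pixels by HSV windows; spec is list(h = c(lo, hi) degrees,
# s_min, v_min). A wrapped hue window (lo > hi) means lo..360 plus 0..hi.
.match_hue <- function(pixels, spec) {
  dm <- dim(pixels)
  rgb <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
               as.vector(pixels[, , 3]))
  rgb <- pmin(pmax(rgb, 0), 255)   # guard against interpolation round-off
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  h <- hsv[1, ] * 360; s <- hsv[2, ]; v <- hsv[3, ]
  hits <- if (spec$h[1] <= spec$h[2]) h >= spec$h[1] & h <= spec$h[2]
          else h >= spec$h[1] | h <= spec$h[2]
  hits <- hits & s >= spec$s_min & v >= spec$v_min
  matrix(hits, dm[1], dm[2])
}

.dilate <- function(m, r) {
  if (r <= 0 || !any(m)) return(m)
  m | sqrt(cpp_edt_sq(!m)) <= r
}

# interior of a set of contour pixels: foreground-complement components that
# do not touch the raster border. Hand-drawn gaps up to 2r are bridged by
# dilating the contour before tracing the interior, then growing the
# interior back by the same radius so no area is lost to the dilation.
.contour_interior <- function(contour, r = 0) {
  cd <- .dilate(contour, r)
  lab <- cpp_label_components(!cd, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- setdiff(border, 0L)
  inside <- !cd & !(matrix(lab %in% border, nrow(lab), ncol(lab)))
  if (r > 0 && any(inside)) inside <- .dilate(inside, r)
  inside & !contour
}

#' Derive the inclusion mask from green/red overlay contours
#'
#' Pixels inside a closed green contour and not inside any red contour are
#' kept. Contour pixels themselves are excluded. Hand-drawn gaps up to
#' `closing_radius_px` are bridged by morphological closing.
#'
#' @param slide `annotated_slide`.
#' @param green_hue_spec,red_hue_spec HSV windows, `list(h = c(lo, hi),
#'   s_min =, v_min =)` with hue in degrees.
#' @param closing_radius_px gap-bridging radius in pixels.
#' @return `region_mask`.
#' @export
build_mask <- function(slide,
                       green_hue_spec = list(h = c(90, 150), s_min = 0.85, v_min = 0.5),
                       red_hue_spec = list(h = c(345, 15), s_min = 0.85, v_min = 0.5),
                       closing_radius_px = 3) {
  stopifnot(inherits(slide, "annotated_slide"))
  green <- .match_hue(slide$pixels, green_hue_spec)
  red <- .match_hue(slide$pixels, red_hue_spec)
  if (!any(green)) stop("no tumour region: no closed green contour found")
  g_in <- .contour_interior(green, closing_radius_px)
  if (!any(g_in)) stop("no tumour region: no closed green contour found")
  r_in <- matrix(FALSE, nrow(green), ncol(green))
  if (any(red)) {
    r_in <- .contour_interior(red, closing_radius_px)
    if (!any(r_in & g_in) && any(red))
      warning("red contour outside any green region; ignored")
  }
  mask <- g_in & !r_in & !green & !red
  region_mask(mask, slide$resolution_um_per_px)
}

#' Orientation of the equal-second-moment ellipse of a mask
#'
#' Angle in degrees in (-90, 90] of the major axis of the ellipse with the
#' same second central moments as the true-pixel set. Counter-clockwise
#' positive with the image y axis pointing down (i.e. the angle is measured
#' in standard orientation with y up).
#'
#' @param mask `region_mask` or logical matrix.
#' @return angle in degrees.
#' @export
orientation_angle <- function(mask) {
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no true pixel")
  if (nrow(idx) == 1L) { warning("single-pixel mask; orientation 0"); return(0) }
  x <- idx[, 2] - mean(idx[, 2])
  yu <- -(idx[, 1] - mean(idx[, 1]))   # y up
  mu20 <- mean(x^2); mu02 <- mean(yu^2); mu11 <- mean(x * yu)
  if (abs(mu11) < 1e-12 && abs(mu20 - mu02) < 1e-12) return(0)
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  # map -90 to the equivalent +90 representative
  if (ang <= -90 + 1e-12) ang <- ang + 180
  ang
}

#' Rotate a slide so the tissue major axis is horizontal, then crop
#'
#' The slide and mask are rotated by minus the orientation angle (bilinear
#' interpolation for RGB, nearest neighbour for the mask so it stays binary)
#' and the frame is shrunk to the bounding box of the true mask pixels.
#' Masked-out pixels are set to black.
#'
#' @param slide `annotated_slide`.
#' @param mask `region_mask` aligned with `slide`.
#' @return list with elements `slide` and `mask` in the rotated, cropped
#'   frame.
#' @export
rotate_and_crop <- function(slide, mask) {
  stopifnot(inherits(slide, "annotated_slide"), inherits(mask, "region_mask"))
  ang <- orientation_angle(mask)
  m <- mask$mask
  px <- slide$pixels
  if (abs(ang) > 1e-9) {
    mrot <- cpp_rotate(m * 1.0, -ang, FALSE, 0) > 0.5
    ch <- lapply(1:3, function(k) cpp_rotate(px[, , k], -ang, TRUE, 0))
    px <- array(0, c(dim(mrot), 3L))
    for (k in 1:3) px[, , k] <- ch[[k]]
    m <- mrot
  }
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  m <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  px <- px[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
  px[array(rep(!m, 3L), dim(px))] <- 0
  list(slide = annotated_slide(px, slide$resolution_um_per_px,
                               slide$magnification_tag),
       mask = region_mask(m, mask$resolution_um_per_px))
}
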