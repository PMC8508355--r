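# Synthetic annotated-slide fixtures built in code.

# blank white slide with a rectangular green contour (1 px line), optional
# red rectangle inside, in pixel coordinates
make_contour_slide <- function(h = 1000, w = 1000, res = 0.908,
                               green = c(250, 250, 749, 749),
                               red = NULL, line_px = 1) {
  img <- array(255, c(h, w, 3))
  draw_rect <- function(img, r0, c0, r1, c1, col, lw) {
    for (l in 0:(lw - 1)) {
      img[c(r0 + l, r1 - l), c0:c1, 1] <- col[1]
      img[c(r0 + l, r1 - l), c0:c1, 2] <- col[2]
      img[c(r0 + l, r1 - l), c0:c1, 3] <- col[3]
      img[r0:r1, c(c0 + l, c1 - l), 1] <- col[1]
      img[r0:r1, c(c0 + l, c1 - l), 2] <- col[2]
      img[r0:r1, c(c0 + l, c1 - l), 3] <- col[3]
    }
    img
  }
  if (!is.null(green))
    img <- draw_rect(img, green[1], green[2], green[3], green[4],
                     c(0, 255, 0), line_px)
  if (!is.null(red))
    img <- draw_rect(img, red[1], red[2], red[3], red[4],
                     c(255, 0, 0), line_px)
  annotated_slide(img, res)
}

# elliptical logical mask tilted by `deg` (ccw, y up), axes a >= b in px
make_ellipse_mask <- function(h, w, a, b, deg, res = 0.908) {
  th <- deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  x <- cols - cx; yu <- -(rows - cy)
  u <- x * cos(th) + yu * sin(th)
  v <- -x * sin(th) + yu * cos(th)
  region_mask((u / a)^2 + (v / b)^2 <= 1, res)
}
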