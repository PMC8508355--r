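# Synthetic data: point patterns with known spatial statistics,
# pseudo-immunohistochemistry renders with hand-drawn-style contours, and
# labelled two-class cohorts. Everything is deterministic given (params,
# seed).

#' Generate a synthetic cell pattern
#'
#' Kinds: `csr` (homogeneous Poisson, or a binomial process when `n` is
#' given), `thomas` (Poisson cluster process: parents of intensity `kappa`
#' per um^2, offspring counts Poisson(`mu`), isotropic Gaussian dispersion
#' `sigma` um -- closed-form K attached as ground truth), `hardcore`
#' (dart-throwing with minimum distance `delta`), `grid`, `line`,
#' `sierpinski` (vertex set of the iterated construction, scaled to the
#' window).
#'
#' @param kind pattern type.
#' @param params list of kind-specific parameters: `lambda_per_mm2` or `n`
#'   (csr), `kappa_per_mm2`, `mu`, `sigma_um`, optionally `n` to condition
#'   on a fixed count (thomas), `n`, `delta_um` (hardcore), `nx`, `ny`
#'   (grid), `n` (line), `iterations` (sierpinski).
#' @param window numeric length-2 window sides in micrometres.
#' @param seed RNG seed.
#' @return `cell_pattern`; ground truth (true intensity, closed-form K
#'   where available) is attached as attribute `ground_truth`.
#' @export
gen_pattern <- function(kind = c("csr", "thomas", "hardcore", "grid", "line",
                                 "sierpinski"),
                        params = list(), window = c(1000, 1000), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  w <- window[1]; h <- window[2]
  area_mm2 <- w * h / 1e6
  gt <- list(kind = kind)
  if (kind == "csr") {
    n <- if (!is.null(params$n)) params$n
    else rpois(1, params$lambda_per_mm2 * area_mm2)
    x <- runif(n, 0, w); y <- runif(n, 0, h)
    gt$true_intensity_per_mm2 <- if (!is.null(params$n)) n / area_mm2
    else params$lambda_per_mm2
    gt$K_true <- function(r) pi * r^2
  } else if (kind == "thomas") {
    kappa <- params$kappa_per_mm2 / 1e6       # per um^2
    mu <- params$mu; sigma <- params$sigma_um
    pad <- 4 * sigma
    np <- rpois(1, kappa * (w + 2 * pad) * (h + 2 * pad))
    px <- runif(np, -pad, w + pad); py <- runif(np, -pad, h + pad)
    no <- rpois(np, mu)
    x <- rep(px, no) + rnorm(sum(no), 0, sigma)
    y <- rep(py, no) + rnorm(sum(no), 0, sigma)
    keep <- x >= 0 & x <= w & y >= 0 & y <= h
    x <- x[keep]; y <- y[keep]
    if (!is.null(params$n)) {
      while (length(x) < params$n) {       # top up with extra clusters
        ex <- runif(1, 0, w); ey <- runif(1, 0, h)
        nn <- rpois(1, mu)
        x <- c(x, ex + rnorm(nn, 0, sigma)); y <- c(y, ey + rnorm(nn, 0, sigma))
        keep <- x >= 0 & x <= w & y >= 0 & y <= h
        x <- x[keep]; y <- y[keep]
      }
      sel <- sample.int(length(x), params$n)
      x <- x[sel]; y <- y[sel]
    }
    gt$true_intensity_per_mm2 <- kappa * mu * 1e6
    gt$K_true <- function(r) pi * r^2 + (1 - exp(-r^2 / (4 * sigma^2))) / kappa
  } else if (kind == "hardcore") {
    n <- params$n; delta <- params$delta_um
    x <- numeric(0); y <- numeric(0)
    attempts <- 0
    while (length(x) < n) {
      attempts <- attempts + 1
      if (attempts > 1e6) stop("hardcore packing infeasible after 1e6 attempts")
      cx <- runif(1, 0, w); cy <- runif(1, 0, h)
      if (!length(x) || min((x - cx)^2 + (y - cy)^2) >= delta^2) {
        x <- c(x, cx); y <- c(y, cy)
      }
    }
    gt$true_intensity_per_mm2 <- n / area_mm2
  } else if (kind == "grid") {
    nx <- params$nx; ny <- params$ny
    gx <- (seq_len(nx) - 0.5) * w / nx
    gy <- (seq_len(ny) - 0.5) * h / ny
    x <- rep(gx, times = ny); y <- rep(gy, each = nx)
    gt$true_intensity_per_mm2 <- nx * ny / area_mm2
  } else if (kind == "line") {
    n <- params$n
    t <- seq(0, 1, length.out = n)
    x <- 0.05 * w + t * 0.9 * w
    y <- rep(h / 2, n) + t * 0   # horizontal segment
    gt$true_intensity_per_mm2 <- n / area_mm2
  } else {  # sierpinski
    # default depth chosen so the finest lattice constant (window / 2^it)
    # sits just below the 10 um minimum box of the box-counting ladder
    it <- if (is.null(params$iterations)) 7L else params$iterations
    pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
    for (i in seq_len(it)) {
      pts <- rbind(pts / 2,
                   sweep(pts / 2, 2, c(0.5, 0), "+"),
                   sweep(pts / 2, 2, c(0.25, sqrt(3) / 4), "+"))
      pts <- unique(round(pts, 12))
    }
    x <- pts[, 1] * w * 0.95 + 0.025 * w
    y <- pts[, 2] * h * 0.95 + 0.025 * h
    gt$true_dimension <- log(3) / log(2)
  }
  p <- cell_pattern(x, y, frame_um = c(w, h))
  attr(p, "ground_truth") <- gt
  p
}

# filled ellipse rasterisation helper (row/col/axes in px)
.draw_ellipse <- function(img, r0, c0, ra, rb, rgb) {
  nr <- dim(img)[1]; nc <- dim(img)[2]
  rr <- max(1, floor(r0 - ra)):min(nr, ceiling(r0 + ra))
  cc <- max(1, floor(c0 - rb)):min(nc, ceiling(c0 + rb))
  if (!length(rr) || !length(cc)) return(img)
  d <- outer((rr - r0)^2 / ra^2, (cc - c0)^2 / rb^2, "+")
  hit <- d <= 1
  for (k in 1:3) {
    sl <- img[rr, cc, k]
    sl[hit] <- rgb[k]
    img[rr, cc, k] <- sl
  }
  img
}

#' Render a pseudo-IHC slide from a pattern
#'
#' Each ground-truth centroid becomes a brown (DAB-like) ellipse on a
#' pink-ish counterstain background with per-image hue jitter and per-pixel
#' texture noise, emulating multi-centre staining variability. A green
#' contour is drawn around the tissue region; optional red boxes mark
#' exclusion areas. The input pattern is attached as attribute
#' `ground_truth_pattern`.
#'
#' @param pattern `cell_pattern`.
#' @param style list: `resolution_um_per_px`, `bg_rgb`, `nucleus_rgb`,
#'   `hue_jitter` (sd, per image), `noise_sd` (per pixel),
#'   `nucleus_radius_um` (mean), `radius_jitter` (sd um), `margin_um`,
#'   `red_boxes` (list of c(x0, y0, x1, y1) um, slide frame).
#' @param seed RNG seed.
#' @return `annotated_slide`.
#' @export
render_ihc <- function(pattern, style = list(), seed = 1) {
  set.seed(seed)
  st <- modifyList(list(resolution_um_per_px = 0.908,
                        bg_rgb = c(232, 205, 215),
                        nucleus_rgb = c(150, 90, 60),
                        hue_jitter = 6, noise_sd = 4,
                        nucleus_radius_um = 4, radius_jitter = 0.4,
                        margin_um = 20, red_boxes = list()), style)
  # modifyList drops unnamed nested lists; take the box list verbatim
  if (!is.null(style$red_boxes)) st$red_boxes <- style$red_boxes
  res <- st$resolution_um_per_px
  mar <- st$margin_um
  wpx <- ceiling((pattern$frame_um[1] + 2 * mar) / res)
  hpx <- ceiling((pattern$frame_um[2] + 2 * mar) / res)
  img <- array(255, c(hpx, wpx, 3))
  # tissue block with per-image hue shift
  bg <- pmin(pmax(st$bg_rgb + rnorm(3, 0, st$hue_jitter), 0), 255)
  t_r0 <- floor(mar / res / 2); t_c0 <- floor(mar / res / 2)
  t_r1 <- hpx - t_r0; t_c1 <- wpx - t_c0
  for (k in 1:3) img[t_r0:t_r1, t_c0:t_c1, k] <- bg[k]
  # nuclei
  nuc <- pmin(pmax(st$nucleus_rgb + rnorm(3, 0, st$hue_jitter), 0), 255)
  for (i in seq_len(pattern$n_cells)) {
    r0 <- (pattern$y_um[i] + mar) / res
    c0 <- (pattern$x_um[i] + mar) / res
    ra <- max(1.2, (st$nucleus_radius_um + rnorm(1, 0, st$radius_jitter)) / res)
    rb <- max(1.2, (st$nucleus_radius_um + rnorm(1, 0, st$radius_jitter)) / res)
    col <- pmin(pmax(nuc + rnorm(3, 0, 4), 0), 255)
    img <- .draw_ellipse(img, r0, c0, ra, rb, col)
  }
  # per-pixel texture noise on the tissue block
  n_noise <- array(rnorm(length(img), 0, st$noise_sd), dim(img))
  img <- pmin(pmax(img + n_noise, 0), 255)
  # green contour rectangle (2 px) just inside the canvas
  g0 <- 2; gr1 <- hpx - 1; gc1 <- wpx - 1
  img[c(g0, g0 + 1, gr1 - 1, gr1), g0:gc1, 1] <- 0
  img[c(g0, g0 + 1, gr1 - 1, gr1), g0:gc1, 2] <- 255
  img[c(g0, g0 + 1, gr1 - 1, gr1), g0:gc1, 3] <- 0
  img[g0:gr1, c(g0, g0 + 1, gc1 - 1, gc1), 1] <- 0
  img[g0:gr1, c(g0, g0 + 1, gc1 - 1, gc1), 2] <- 255
  img[g0:gr1, c(g0, g0 + 1, gc1 - 1, gc1), 3] <- 0
  # red exclusion boxes (outline)
  for (bx in st$red_boxes) {
    r0 <- round((bx[2] + mar) / res); r1 <- round((bx[4] + mar) / res)
    c0 <- round((bx[1] + mar) / res); c1 <- round((bx[3] + mar) / res)
    rs <- max(3, r0):min(hpx - 2, r1); cs <- max(3, c0):min(wpx - 2, c1)
    for (k in 1:3) {
      img[c(rs[1], rs[1] + 1, rs[length(rs)] - 1, rs[length(rs)]), cs, k] <-
        c(255, 0, 0)[k]
      img[rs, c(cs[1], cs[1] + 1, cs[length(cs)] - 1, cs[length(cs)]), k] <-
        c(255, 0, 0)[k]
    }
  }
  sl <- annotated_slide(img, res)
  attr(sl, "ground_truth_pattern") <- pattern
  attr(sl, "margin_um") <- mar
  sl
}

#' Generate a labelled synthetic cohort with full feature extraction
#'
#' Good-prognosis samples are complete-spatial-randomness patterns; poor
#' prognosis samples are Thomas cluster patterns. With
#' `intensity_matched = TRUE` (default) every sample has exactly
#' `n_cells` cells in the same window, so counting-based descriptors carry
#' no class signal while the spatial arrangement does. The pseudo labelling
#' index is a noisy monotone function of density.
#'
#' @param n_per_class samples per class.
#' @param n_cells cells per sample (matched).
#' @param window window sides in um.
#' @param cluster list with `kappa_per_mm2`, `mu`, `sigma_um` for the PP
#'   class.
#' @param intensity_matched condition both classes on `n_cells` points.
#' @param li_noise_sd noise on the pseudo labelling index.
#' @param seed RNG seed.
#' @return list of class `cohort`: `features` (2 * n_per_class x 490
#'   data.frame), `labels`, `histology`, `ki67_li`, `density_per_mm2`,
#'   `patterns`.
#' @export
gen_cohort <- function(n_per_class = 20, n_cells = 300,
                       window = c(1000, 1000),
                       cluster = list(kappa_per_mm2 = 20, mu = 15,
                                      sigma_um = 25),
                       intensity_matched = TRUE, li_noise_sd = 2, seed = 1) {
  n_tot <- 2 * n_per_class
  labels <- rep(c("GP", "PP"), each = n_per_class)
  pats <- vector("list", n_tot)
  feats <- matrix(NA_real_, n_tot, nrow(feature_schema()),
                  dimnames = list(NULL, feature_schema()$name))
  for (i in seq_len(n_tot)) {
    si <- seed * 10000L + i
    if (labels[i] == "GP") {
      prm <- if (intensity_matched) list(n = n_cells)
      else list(lambda_per_mm2 = n_cells / (prod(window) / 1e6))
      pats[[i]] <- gen_pattern("csr", prm, window, seed = si)
    } else {
      prm <- c(cluster, if (intensity_matched) list(n = n_cells))
      pats[[i]] <- gen_pattern("thomas", prm, window, seed = si)
    }
    feats[i, ] <- extract_features(pats[[i]])
  }
  set.seed(seed)
  density <- vapply(pats, function(p) p$density_per_mm2, numeric(1))
  ki67_li <- pmax(0.5, density / 25 + rnorm(n_tot, 0, li_noise_sd))
  histology <- sample(c("AC", "LCNEC"), n_tot, replace = TRUE)
  structure(list(features = as.data.frame(feats, check.names = FALSE),
                 labels = labels, histology = histology, ki67_li = ki67_li,
                 density_per_mm2 = density, patterns = pats),
            class = "cohort")
}
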