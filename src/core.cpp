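#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Connected-component labelling of a binary raster.
// connectivity is 4 or 8; background (false) pixels get label 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix img, int connectivity) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int dr8[] = {-1,-1,-1, 0, 0, 1, 1, 1};
  int dc8[] = {-1, 0, 1,-1, 1,-1, 0, 1};
  int dr4[] = {-1, 1, 0, 0};
  int dc4[] = { 0, 0,-1, 1};
  int ndir = (connectivity == 8) ? 8 : 4;
  int *dr = (connectivity == 8) ? dr8 : dr4;
  int *dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    if (!img(r, c) || lab(r, c) != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(r + c * nr);
    lab(r, c) = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pr = p % nr, pc = p / nr;
      for (int d = 0; d < ndir; ++d) {
        int qr = pr + dr[d], qc = pc + dc[d];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (img(qr, qc) && lab(qr, qc) == 0) {
          lab(qr, qc) = next;
          stack.push_back(qr + qc * nr);
        }
      }
    }
  }
  return lab;
}

static void edt_1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  // Felzenszwalb & Huttenlocher lower-envelope squared distance transform.
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance of every true pixel to the nearest false
// pixel (pixels outside the raster count as background).
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix g(nr, nc);
  const double INF = 1e30;
  // column pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = img(r, c) ? INF : 0.0;
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) g(r, c) = d[c];
  }
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r)
    if (!img(r, c)) g(r, c) = 0.0;
  return g;
}

// Median filter with replicate padding, square window of odd side k.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int k) {
  int nr = img.nrow(), nc = img.ncol();
  if (k > nr || k > nc) stop("median kernel larger than image");
  int h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k * k);
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    int m = 0;
    for (int dc = -h; dc <= h; ++dc) for (int dr = -h; dr <= h; ++dr) {
      int rr = std::min(std::max(r + dr, 0), nr - 1);
      int cc = std::min(std::max(c + dc, 0), nc - 1);
      buf[m++] = img(rr, cc);
    }
    std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
    double med = buf[m / 2];
    if (m % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
      med = 0.5 * (med + lo);
    }
    out(r, c) = med;
  }
  return out;
}

// Rotate a single-channel raster by `deg` counter-clockwise (y axis pointing
// down, so visually counter-clockwise in standard orientation with y up).
// Output canvas is the bounding box of the rotated input. bilinear = false
// gives nearest-neighbour (for masks).
// [[Rcpp::export]]
NumericMatrix cpp_rotate(NumericMatrix img, double deg, bool bilinear, double bg) {
  int nr = img.nrow(), nc = img.ncol();
  double th = deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  // rotation acting on (x, y_up): x' = x ct - y st ; y' = x st + y ct.
  // rows increase downwards: y_up = -(row).
  double w = nc, h = nr;
  double outw = std::fabs(w * ct) + std::fabs(h * st);
  double outh = std::fabs(w * st) + std::fabs(h * ct);
  int onr = (int)std::ceil(outh - 1e-9), onc = (int)std::ceil(outw - 1e-9);
  NumericMatrix out(onr, onc);
  double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
  double ox = (onc - 1) / 2.0, oy = (onr - 1) / 2.0;
  for (int c = 0; c < onc; ++c) for (int r = 0; r < onr; ++r) {
    double x = c - ox, yu = -(r - oy);
    // inverse rotation
    double xs = x * ct + yu * st;
    double ys = -x * st + yu * ct;
    double sc = xs + cx, sr = -ys + cy;
    if (bilinear) {
      int c0 = (int)std::floor(sc), r0 = (int)std::floor(sr);
      double fc = sc - c0, fr = sr - r0;
      double acc = 0.0, wsum = 0.0;
      for (int dc = 0; dc <= 1; ++dc) for (int dr = 0; dr <= 1; ++dr) {
        int rr = r0 + dr, cc = c0 + dc;
        double wgt = (dc ? fc : 1 - fc) * (dr ? fr : 1 - fr);
        if (wgt <= 0) continue;
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) { acc += wgt * img(rr, cc); wsum += wgt; }
      }
      out(r, c) = (wsum > 0) ? acc / wsum : bg;
    } else {
      int rr = (int)std::lround(sr), cc = (int)std::lround(sc);
      out(r, c) = (rr >= 0 && rr < nr && cc >= 0 && cc < nc) ? img(rr, cc) : bg;
    }
  }
  return out;
}

// Translation-corrected Ripley sums: for each radius, sum over ordered pairs
// i != j with d_ij <= r of the translation weight a*b/((a-|dx|)(b-|dy|)),
// where (a, b) are the sides of the bounding rectangle of the window.
// [[Rcpp::export]]
NumericVector cpp_ripley_sums(NumericVector x, NumericVector y,
                              NumericVector radii, double a, double b) {
  int n = x.size(), m = radii.size();
  NumericVector out(m);
  double rmax = 0.0;
  for (int k = 0; k < m; ++k) rmax = std::max(rmax, radii[k]);
  double rmax2 = rmax * rmax;
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double dx = std::fabs(x[i] - x[j]), dy = std::fabs(y[i] - y[j]);
    double d2 = dx * dx + dy * dy;
    if (d2 > rmax2) continue;
    double w = (a * b) / ((a - dx) * (b - dy));
    double d = std::sqrt(d2);
    for (int k = 0; k < m; ++k) if (d <= radii[k]) out[k] += 2.0 * w;
  }
  return out;
}

// All unordered pairs with Euclidean distance <= thr (1-based indices).
// [[Rcpp::export]]
IntegerMatrix cpp_edge_list(NumericVector x, NumericVector y, double thr) {
  int n = x.size();
  double t2 = thr * thr;
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double dx = x[i] - x[j], dy = y[i] - y[j];
    if (dx * dx + dy * dy <= t2) { ei.push_back(i + 1); ej.push_back(j + 1); }
  }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) { out(k, 0) = ei[k]; out(k, 1) = ej[k]; }
  return out;
}

// Greedy seed picking: candidate pixels ordered by decreasing distance value,
// accepted when no already-accepted seed of the same component lies within
// min_sep pixels. Returns rows (row, col, comp), 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_pick_seeds(NumericMatrix dist, IntegerMatrix comp,
                             double min_sep, double min_val) {
  int nr = dist.nrow(), nc = dist.ncol();
  std::vector<int> idx;
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r)
    if (comp(r, c) > 0 && dist(r, c) >= min_val) idx.push_back(r + c * nr);
  std::stable_sort(idx.begin(), idx.end(), [&](int p, int q) {
    double dp = dist(p % nr, p / nr), dq = dist(q % nr, q / nr);
    if (dp != dq) return dp > dq;
    return p < q;
  });
  std::vector<int> sr, sc, scomp;
  double sep2 = min_sep * min_sep;
  int win = (int)std::ceil(min_sep);
  for (int p : idx) {
    int r = p % nr, c = p / nr, cp = comp(r, c);
    // must be a local maximum of the distance map within min_sep
    bool ok = true;
    double v = dist(r, c);
    for (int dc = -win; dc <= win && ok; ++dc) for (int dr = -win; dr <= win; ++dr) {
      if (dr * dr + dc * dc > sep2) continue;
      int rr = r + dr, cc = c + dc;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (comp(rr, cc) == cp && dist(rr, cc) > v) { ok = false; break; }
    }
    if (!ok) continue;
    for (size_t s = 0; s < sr.size(); ++s) {
      if (scomp[s] != cp) continue;
      double dr = sr[s] - r, dc = sc[s] - c;
      if (dr * dr + dc * dc < sep2) { ok = false; break; }
    }
    if (ok) { sr.push_back(r); sc.push_back(c); scomp.push_back(cp); }
  }
  IntegerMatrix out(sr.size(), 3);
  for (size_t s = 0; s < sr.size(); ++s) {
    out(s, 0) = sr[s] + 1; out(s, 1) = sc[s] + 1; out(s, 2) = scomp[s];
  }
  return out;
}

// Split touching blobs: every foreground pixel is reassigned to the nearest
// seed of its connected component (Voronoi split of each blob, equivalent to
// watershed of the negated distance transform for convex nucleus shapes).
// seeds: matrix (row, col, comp) 1-based. Returns per-pixel seed index.
// [[Rcpp::export]]
IntegerMatrix cpp_split_by_seeds(IntegerMatrix comp, IntegerMatrix seeds) {
  int nr = comp.nrow(), nc = comp.ncol();
  int ns = seeds.nrow();
  IntegerMatrix out(nr, nc);
  // group seeds by component
  int maxc = 0;
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) maxc = std::max(maxc, comp(r, c));
  std::vector<std::vector<int>> bycomp(maxc + 1);
  for (int s = 0; s < ns; ++s) bycomp[seeds(s, 2)].push_back(s);
  for (int c = 0; c < nc; ++c) for (int r = 0; r < nr; ++r) {
    int cp = comp(r, c);
    if (cp == 0) { out(r, c) = 0; continue; }
    const std::vector<int> &ss = bycomp[cp];
    if (ss.empty()) { out(r, c) = 0; continue; }
    int best = ss[0];
    double bd = 1e30;
    for (int s : ss) {
      double dr = seeds(s, 0) - 1 - r, dc = seeds(s, 1) - 1 - c;
      double d2 = dr * dr + dc * dc;
      if (d2 < bd) { bd = d2; best = s; }
    }
    out(r, c) = best + 1;
  }
  return out;
}

// NCA stochastic-gradient solver: per-sample updates of feature weights w
// maximising p_i - lambda/n * sum w^2. Dflat is the (n*n) x p matrix of
// per-feature absolute differences (column-major pair index i + j*n,
// 0-based); same(i,j) = 1 for same-class pairs, diagonal 0. ord holds the
// 1-based visit order for each pass (rows = passes), drawn with R's RNG so
// results stay seed-reproducible.
// [[Rcpp::export]]
NumericVector cpp_nca_sgd(NumericMatrix Dflat, NumericMatrix same, int n,
                          IntegerMatrix ord, double lambda, double eta0) {
  int p = Dflat.ncol();
  int passes = ord.nrow();
  NumericVector w(p, 1.0);
  std::vector<double> w2(p), d(n), pij(n), gs(p), gsame(p);
  double t = 0.0;
  double half = n * passes / 2.0;
  for (int pass = 0; pass < passes; ++pass) {
    for (int oi = 0; oi < n; ++oi) {
      int i = ord(pass, oi) - 1;
      t += 1.0;
      for (int l = 0; l < p; ++l) w2[l] = w[l] * w[l];
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        const double *col;
        // row index in Dflat for pair (i, j)
        int r = i + j * n;
        for (int l = 0; l < p; ++l) acc += Dflat(r, l) * w2[l];
        d[j] = acc;
      }
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        pij[j] = (j == i) ? 0.0 : std::exp(-d[j]);
        s += pij[j];
      }
      if (s > 0) for (int j = 0; j < n; ++j) pij[j] /= s;
      double p_i = 0.0;
      for (int j = 0; j < n; ++j) if (same(i, j) > 0.5) p_i += pij[j];
      std::fill(gs.begin(), gs.end(), 0.0);
      std::fill(gsame.begin(), gsame.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (pij[j] == 0.0) continue;
        int r = i + j * n;
        double pj = pij[j];
        bool sm = same(i, j) > 0.5;
        for (int l = 0; l < p; ++l) {
          double v = Dflat(r, l) * pj;
          gs[l] += v;
          if (sm) gsame[l] += v;
        }
      }
      double eta = eta0 / (1.0 + t / half);
      for (int l = 0; l < p; ++l) {
        // stochastic gradient of p_i - lambda*sum(w^2): the regulariser
        // appears in full in every per-sample objective
        double g = 2.0 * w[l] * (p_i * gs[l] - gsame[l]) -
          2.0 * lambda * w[l];
        w[l] += eta * g;
      }
    }
  }
  for (int l = 0; l < p; ++l) w[l] = std::fabs(w[l]);
  return w;
}
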