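// Per-pixel GLCM Haralick features and windowed first-order statistics.
// Images arrive as integer-quantized matrices (levels 0..G-1) in column-major
// R layout; borders use reflect padding. Co-occurrence pairs are accumulated
// inside the (2r+1)^2 window patch only (both pixels of a pair must fall
// inside the patch), symmetric and normalized, one GLCM per offset; the 14
// statistics are computed per offset and averaged.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int reflect(int i, int n) {
  // reflect without repeating the edge pixel (R's "symmetric" style: abcb a)
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// 14 Haralick statistics of one normalized symmetric GLCM restricted to the
// active gray levels. Levels are 1-based gray-tone values (level + 1).
static void haralickStats(const arma::mat& p, const arma::uvec& levels,
                          double* out) {
  const int G = p.n_rows;
  arma::vec px = arma::sum(p, 1);
  arma::vec py = px; // symmetric
  double mux = 0, muy = 0;
  for (int i = 0; i < G; ++i) mux += (levels(i) + 1.0) * px(i);
  muy = mux;
  double sx2 = 0;
  for (int i = 0; i < G; ++i)
    sx2 += (levels(i) + 1.0 - mux) * (levels(i) + 1.0 - mux) * px(i);
  double sy2 = sx2;

  double energy = 0, contrast = 0, corrnum = 0, variance = 0, idm = 0;
  double entropy = 0, hxy1 = 0;
  const int Lmax = levels(G - 1) + 1;                 // largest gray tone
  arma::vec psum(2 * Lmax + 1, arma::fill::zeros);    // indexed by tone sum
  arma::vec pdiff(Lmax + 1, arma::fill::zeros);       // |tone difference|
  for (int i = 0; i < G; ++i) {
    double li = levels(i) + 1.0;
    for (int j = 0; j < G; ++j) {
      double pij = p(i, j);
      if (pij <= 0) continue;
      double lj = levels(j) + 1.0;
      energy += pij * pij;
      contrast += (li - lj) * (li - lj) * pij;
      corrnum += li * lj * pij;
      variance += (li - mux) * (li - mux) * pij;
      idm += pij / (1.0 + (li - lj) * (li - lj));
      entropy -= pij * std::log(pij);
      double pp = px(i) * py(j);
      if (pp > 0) hxy1 -= pij * std::log(pp);
      psum((int)(li + lj)) += pij;
      pdiff((int)std::abs(li - lj)) += pij;
    }
  }
  double sumavg = 0, sumvar = 0, sument = 0;
  for (arma::uword k = 0; k < psum.n_elem; ++k) {
    double q = psum(k);
    if (q <= 0) continue;
    sumavg += k * q;
    sument -= q * std::log(q);
  }
  for (arma::uword k = 0; k < psum.n_elem; ++k) {
    double q = psum(k);
    if (q > 0) sumvar += (k - sumavg) * (k - sumavg) * q;
  }
  double davg = 0, dvar = 0, dent = 0;
  for (arma::uword k = 0; k < pdiff.n_elem; ++k) {
    double q = pdiff(k);
    if (q <= 0) continue;
    davg += k * q;
    dent -= q * std::log(q);
  }
  for (arma::uword k = 0; k < pdiff.n_elem; ++k) {
    double q = pdiff(k);
    if (q > 0) dvar += (k - davg) * (k - davg) * q;
  }
  double hx = 0, hxy2 = 0;
  for (int i = 0; i < G; ++i)
    if (px(i) > 0) hx -= px(i) * std::log(px(i));
  for (int i = 0; i < G; ++i)
    for (int j = 0; j < G; ++j) {
      double pp = px(i) * py(j);
      if (pp > 0) hxy2 -= pp * std::log(pp);
    }
  double hy = hx;
  double correlation = 0;
  double sxy = std::sqrt(sx2 * sy2);
  if (sxy > 1e-12) correlation = (corrnum - mux * muy) / sxy;
  double denom = std::max(hx, hy);
  double imc1 = (denom > 1e-12) ? (entropy - hxy1) / denom : 0.0;
  double arg = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
  double imc2 = (arg > 0) ? std::sqrt(arg) : 0.0;

  // maximal correlation coefficient: sqrt of second-largest eigenvalue of
  // Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
  double mcc = 0.0;
  if (G >= 2) {
    arma::mat Q(G, G, arma::fill::zeros);
    bool ok = true;
    for (int i = 0; i < G && ok; ++i) {
      if (px(i) <= 0) { ok = false; break; }
      for (int j = 0; j < G; ++j) {
        double s = 0;
        for (int k = 0; k < G; ++k)
          if (py(k) > 0) s += p(i, k) * p(j, k) / (px(i) * py(k));
        Q(i, j) = s;
      }
    }
    if (ok) {
      arma::cx_vec ev;
      bool done = arma::eig_gen(ev, Q);
      if (done && ev.n_elem >= 2) {
        arma::vec re = arma::sort(arma::real(ev), "descend");
        double second = re(1);
        if (second < 0) second = 0;
        if (second > 1) second = 1;
        mcc = std::sqrt(second);
      }
    }
  }

  out[0] = energy;   out[1] = contrast; out[2] = correlation;
  out[3] = variance; out[4] = idm;      out[5] = sumavg;
  out[6] = sumvar;   out[7] = sument;   out[8] = entropy;
  out[9] = dvar;     out[10] = dent;    out[11] = imc1;
  out[12] = imc2;    out[13] = mcc;
}

// [[Rcpp::export(name = ".haralickCpp")]]
NumericMatrix haralickCpp(IntegerMatrix img, int window,
                          IntegerMatrix offsets, int grayLevels) {
  const int H = img.nrow(), W = img.ncol();
  const int r = window / 2;
  const int nOff = offsets.nrow();
  NumericMatrix out(H * W, 14);
  double stats[14], acc[14];

  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      // window patch with reflect padding
      arma::imat patch(window, window);
      for (int dx = -r; dx <= r; ++dx)
        for (int dy = -r; dy <= r; ++dy)
          patch(dy + r, dx + r) = img(reflect(y + dy, H), reflect(x + dx, W));
      // active levels in patch
      std::vector<int> lvl2idx(grayLevels, -1);
      std::vector<int> lvls;
      for (int i = 0; i < window * window; ++i) {
        int v = patch(i % window, i / window);
        if (lvl2idx[v] < 0) { lvl2idx[v] = lvls.size(); lvls.push_back(v); }
      }
      std::sort(lvls.begin(), lvls.end());
      for (size_t i = 0; i < lvls.size(); ++i) lvl2idx[lvls[i]] = i;
      const int G = lvls.size();
      arma::uvec levels(G);
      for (int i = 0; i < G; ++i) levels(i) = lvls[i];

      for (int f = 0; f < 14; ++f) acc[f] = 0;
      for (int o = 0; o < nOff; ++o) {
        int dy = offsets(o, 0), dx = offsets(o, 1);
        arma::mat glcm(G, G, arma::fill::zeros);
        double total = 0;
        for (int px_ = 0; px_ < window; ++px_)
          for (int py_ = 0; py_ < window; ++py_) {
            int qy = py_ + dy, qx = px_ + dx;
            if (qy < 0 || qy >= window || qx < 0 || qx >= window) continue;
            int a = lvl2idx[patch(py_, px_)];
            int b = lvl2idx[patch(qy, qx)];
            glcm(a, b) += 1; glcm(b, a) += 1; // symmetric
            total += 2;
          }
        if (total > 0) glcm /= total;
        haralickStats(glcm, levels, stats);
        for (int f = 0; f < 14; ++f) acc[f] += stats[f];
      }
      for (int f = 0; f < 14; ++f) out(x * H + y, f) = acc[f] / nOff;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".firstOrderCpp")]]
NumericMatrix firstOrderCpp(NumericMatrix img, int window) {
  const int H = img.nrow(), W = img.ncol();
  const int r = window / 2;
  const int n = window * window;
  NumericMatrix out(H * W, 4); // mean, median, sd, range
  std::vector<double> buf(n);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int k = 0;
      double s = 0, mn = R_PosInf, mx = R_NegInf;
      for (int dx = -r; dx <= r; ++dx)
        for (int dy = -r; dy <= r; ++dy) {
          double v = img(reflect(y + dy, H), reflect(x + dx, W));
          buf[k++] = v; s += v;
          if (v < mn) mn = v;
          if (v > mx) mx = v;
        }
      double mean = s / n;
      double ss = 0;
      for (int i = 0; i < n; ++i) ss += (buf[i] - mean) * (buf[i] - mean);
      std::sort(buf.begin(), buf.end());
      double med = (n % 2) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
      int idx = x * H + y;
      out(idx, 0) = mean;
      out(idx, 1) = med;
      out(idx, 2) = std::sqrt(ss / (n - 1));
      out(idx, 3) = mx - mn;
    }
  return out;
}
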