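// One batch step of Gaussian-kernel mean shift: every active trajectory is
// moved to the kernel-weighted mean of the (fixed) source points. Weights
// below exp(-12) are treated as zero (relative error < 1e-5 on the local
// mean), which bounds the kernel support at sqrt(24) * h; for
// low-dimensional data (d <= 4) a uniform grid over the
// source points prunes pairs outside that support. Memory stays O(U * d).

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

static const double CUTOFF = 12.0;   // exp(-12) ~ 6e-6: negligible weight

static inline void accumulate(const double* y, const double* xj,
                              arma::uword d, double inv2h2,
                              double& wsum, double* acc) {
  double sq = 0;
  for (arma::uword k = 0; k < d; ++k) {
    double diff = y[k] - xj[k];
    sq += diff * diff;
  }
  double e = sq * inv2h2;
  if (e > CUTOFF) return;
  double w = std::exp(-e);
  wsum += w;
  for (arma::uword k = 0; k < d; ++k) acc[k] += w * xj[k];
}

// [[Rcpp::export(name = ".msStepCpp")]]
arma::mat msStepCpp(const arma::mat& Y, const arma::mat& X, double h) {
  const arma::uword U = Y.n_rows, R = X.n_rows, d = X.n_cols;
  const arma::mat Xt = X.t();          // d x R: contiguous point access
  const arma::mat Yt = Y.t();
  arma::mat outT(d, U);
  const double inv2h2 = 1.0 / (2.0 * h * h);
  const double radius = std::sqrt(2.0 * CUTOFF) * h; // kernel support bound
  std::vector<double> acc(d);

  const bool useGrid = (d <= 4) && (R > 512);
  std::unordered_map<long long, std::vector<int> > grid;
  arma::vec lo(d);
  if (useGrid) {
    for (arma::uword k = 0; k < d; ++k) lo(k) = X.col(k).min();
    grid.reserve(R);
    for (arma::uword j = 0; j < R; ++j) {
      long long key = 0;
      for (arma::uword k = 0; k < d; ++k) {
        long long c = (long long)std::floor((Xt(k, j) - lo(k)) / radius);
        key = key * 4096 + (c + 1024);
      }
      grid[key].push_back((int)j);
    }
  }

  for (arma::uword u = 0; u < U; ++u) {
    double wsum = 0;
    std::fill(acc.begin(), acc.end(), 0.0);
    const double* y = Yt.colptr(u);
    if (useGrid) {
      // scan the 3^d cell neighborhood of the trajectory's cell
      std::vector<long long> cells(1, 0);
      for (arma::uword k = 0; k < d; ++k) {
        long long c = (long long)std::floor((y[k] - lo(k)) / radius);
        std::vector<long long> next;
        next.reserve(cells.size() * 3);
        for (size_t b = 0; b < cells.size(); ++b)
          for (int off = -1; off <= 1; ++off)
            next.push_back(cells[b] * 4096 + (c + off + 1024));
        cells.swap(next);
      }
      for (size_t b = 0; b < cells.size(); ++b) {
        std::unordered_map<long long, std::vector<int> >::const_iterator
          hit = grid.find(cells[b]);
        if (hit == grid.end()) continue;
        const std::vector<int>& members = hit->second;
        for (size_t m = 0; m < members.size(); ++m)
          accumulate(y, Xt.colptr(members[m]), d, inv2h2, wsum, &acc[0]);
      }
    } else {
      for (arma::uword j = 0; j < R; ++j)
        accumulate(y, Xt.colptr(j), d, inv2h2, wsum, &acc[0]);
    }
    if (wsum > 0)
      for (arma::uword k = 0; k < d; ++k) outT(k, u) = acc[k] / wsum;
    else
      outT.col(u) = Yt.col(u);
  }
  return outT.t();
}

// row-wise medians of an n x K matrix (used for the elementwise median of a
// distance stack without apply() overhead)
// [[Rcpp::export(name = ".rowMediansCpp")]]
arma::vec rowMediansCpp(const arma::mat& A) {
  const arma::uword n = A.n_rows;
  arma::vec out(n);
  for (arma::uword i = 0; i < n; ++i)
    out(i) = arma::median(A.row(i));
  return out;
}
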