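// Kaiser-Bessel gridding primitives for the non-uniform FFT.
// Positions are continuous 0-based oversampled-grid indices; the kernel is
// separable and wrapped periodically (standard gridding convention).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline double kb(double u, double w, double beta) {
  double t = 2.0 * u / w;
  double s = 1.0 - t * t;
  if (s <= 0.0) return 0.0;
  return R::bessel_i(beta * std::sqrt(s), 0.0, 2.0) *
         std::exp(beta * std::sqrt(s));  // scaled bessel avoids overflow
}

// per-sample separable kernel weights along one axis
static inline void axis_weights(double p, int w, double beta,
                                int n, int *idx, double *wt) {
  int lo = (int)std::ceil(p - w / 2.0);
  for (int a = 0; a < w; ++a) {
    int g = lo + a;
    wt[a] = kb(g - p, (double)w, beta);
    int gm = g % n; if (gm < 0) gm += n;
    idx[a] = gm;
  }
}

// [[Rcpp::export]]
arma::cx_vec kb_interp3(const arma::cx_cube &grid, const arma::mat &pos,
                        int width, double beta) {
  const int n0 = grid.n_rows, n1 = grid.n_cols, n2 = grid.n_slices;
  const arma::uword m = pos.n_rows;
  arma::cx_vec out(m, arma::fill::zeros);
  std::vector<int> ix(width), iy(width), iz(width);
  std::vector<double> wx(width), wy(width), wz(width);
  for (arma::uword j = 0; j < m; ++j) {
    axis_weights(pos(j, 0), width, beta, n0, ix.data(), wx.data());
    axis_weights(pos(j, 1), width, beta, n1, iy.data(), wy.data());
    axis_weights(pos(j, 2), width, beta, n2, iz.data(), wz.data());
    std::complex<double> acc(0.0, 0.0);
    for (int c = 0; c < width; ++c) {
      if (wz[c] == 0.0) continue;
      for (int b = 0; b < width; ++b) {
        double wyz = wy[b] * wz[c];
        if (wyz == 0.0) continue;
        for (int a = 0; a < width; ++a)
          acc += wx[a] * wyz * grid(ix[a], iy[b], iz[c]);
      }
    }
    out(j) = acc;
  }
  return out;
}

// [[Rcpp::export]]
arma::cx_cube kb_spread3(const arma::cx_vec &vals, const arma::mat &pos,
                         int n, int width, double beta) {
  arma::cx_cube grid(n, n, n, arma::fill::zeros);
  const arma::uword m = pos.n_rows;
  std::vector<int> ix(width), iy(width), iz(width);
  std::vector<double> wx(width), wy(width), wz(width);
  for (arma::uword j = 0; j < m; ++j) {
    axis_weights(pos(j, 0), width, beta, n, ix.data(), wx.data());
    axis_weights(pos(j, 1), width, beta, n, iy.data(), wy.data());
    axis_weights(pos(j, 2), width, beta, n, iz.data(), wz.data());
    std::complex<double> v = vals(j);
    for (int c = 0; c < width; ++c) {
      if (wz[c] == 0.0) continue;
      for (int b = 0; b < width; ++b) {
        double wyz = wy[b] * wz[c];
        if (wyz == 0.0) continue;
        std::complex<double> vyz = v * wyz;
        for (int a = 0; a < width; ++a)
          grid(ix[a], iy[b], iz[c]) += wx[a] * vyz;
      }
    }
  }
  return grid;
}

// Direct (brute-force) non-uniform DFT sums; the independent oracle used by
// the test-suite stays in R, but small direct sums are also needed at run
// time for axis-profile PSF evaluation.
// sign = -1: forward (image -> k), sign = +1: adjoint (k -> points).
// [[Rcpp::export]]
arma::cx_vec ndft_sum(const arma::cx_vec &amps, const arma::mat &r,
                      const arma::mat &k, double sign) {
  const arma::uword nk = k.n_rows, nr = r.n_rows;
  arma::cx_vec out(nk, arma::fill::zeros);
  for (arma::uword j = 0; j < nk; ++j) {
    std::complex<double> acc(0.0, 0.0);
    for (arma::uword i = 0; i < nr; ++i) {
      double ph = sign * 2.0 * M_PI *
        (k(j, 0) * r(i, 0) + k(j, 1) * r(i, 1) + k(j, 2) * r(i, 2));
      acc += amps(i) * std::complex<double>(std::cos(ph), std::sin(ph));
    }
    out(j) = acc;
  }
  return out;
}
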