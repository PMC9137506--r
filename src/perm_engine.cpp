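// Compiled core of the permutation engine: per-subject GLM contrast maps
// under row-permuted performance matrices, separable Gaussian smoothing,
// and the across-subject median/extrema scan. The algebra mirrors the R
// reference path (subject_map + smooth_map + median_map) exactly; tests
// assert their agreement.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Moore-Penrose pseudo-inverse of a symmetric matrix via SVD, with the
// numerical rank (singular values below rtol * largest treated as zero).
static mat pinv_with_rank(const mat &A, const double rtol, int &rank) {
  mat U, V;
  vec s;
  svd(U, s, V, A);
  const double tol = rtol * (s.n_elem > 0 ? s.max() : 0.0);
  vec sinv(s.n_elem, fill::zeros);
  rank = 0;
  for (uword i = 0; i < s.n_elem; ++i) {
    if (s(i) > tol) {
      sinv(i) = 1.0 / s(i);
      ++rank;
    }
  }
  return V * diagmat(sinv) * U.t();
}

// In-place separable 3D smoothing of a flattened (d1*d2*d3) map via the
// three banded axis kernels, followed by division by the in-grid
// normalizer W (precomputed in R by pushing an all-ones map through the
// same kernels).
static void smooth_inplace(vec &v, const mat &K1, const mat &K2,
                           const mat &K3, const vec &W, const int d1,
                           const int d2, const int d3) {
  cube c(v.memptr(), d1, d2, d3, false, true);
  const mat K2t = K2.t();
  for (int k = 0; k < d3; ++k)
    c.slice(k) = K1 * c.slice(k) * K2t;
  mat flat(v.memptr(), d1 * d2, d3, false, true);
  flat = flat * K3.t();
  v /= W;
}

// Smoothed contrast t-maps for one subject under B row permutations of
// its performance matrix. Returns a V x B matrix (columns = runs).
// [[Rcpp::export]]
arma::mat cpp_subject_perm_maps(
    const arma::mat &Nc,        // n x 7 centered nuisance block
    const arma::mat &NtY,       // 7 x V nuisance' * Yc
    const arma::mat &HtYT,      // V x n, t(H' Yc)
    const arma::vec &HtY_total, // V, column total of t(H'Yc)
    const arma::vec &yty,       // V, sum of squares of centered series
    const arma::mat &H,         // n x n HRF Toeplitz matrix
    const arma::imat &perms,    // n x B permutations (1-based)
    const Rcpp::IntegerVector &outcome, // n trial outcomes in 1..4
    const int major,            // most frequent outcome (1-based)
    const arma::vec &C,         // length-11 contrast
    const arma::uvec &mask0,    // zero-based indices of in-mask voxels
    const arma::mat &K1, const arma::mat &K2, const arma::mat &K3,
    const arma::vec &W, const int d1, const int d2, const int d3,
    const double rtol) {
  const int n = Nc.n_rows;
  const int V = HtYT.n_rows;
  const int B = perms.n_cols;
  const mat NtYT = NtY.t(); // V x 7
  mat out(V, B);
  std::vector<char> inmask(V, 0);
  for (uword m = 0; m < mask0.n_elem; ++m) inmask[mask0(m)] = 1;

  mat Zp(n, 4);
  mat EtYT(V, 4);
  vec tvec(V);
  for (int b = 0; b < B; ++b) {
    // permuted outcome labels and one-hot event matrix
    Zp.zeros();
    EtYT.zeros();
    vec rest = HtY_total;
    for (int i = 0; i < n; ++i) {
      const int src = perms(i, b) - 1;  // Zp row i = Z row perms(i)
      const int j = outcome[src] - 1;
      Zp(i, j) = 1.0;
      if (j != major - 1) {
        // event block of X'y: sum of t(H'Yc) columns over each minority
        // outcome; the majority row comes from the fixed total
        EtYT.col(j) += HtYT.col(i);
      }
    }
    for (int j = 0; j < 4; ++j)
      if (j != major - 1) rest -= EtYT.col(j);
    EtYT.col(major - 1) = rest;

    mat E = H * Zp;
    E.each_row() -= mean(E, 0);
    mat X = join_rows(Nc, E);
    int rank = 0;
    const mat G = pinv_with_rank(X.t() * X, rtol, rank);
    const double df = n - 1 - rank;
    const double ctgc = as_scalar(C.t() * G * C);

    const mat XtYT = join_rows(NtYT, EtYT); // V x 11
    const mat BT = XtYT * G;                // V x 11 coefficient estimates
    const vec num = BT * C;
    const vec quad = sum(XtYT % BT, 1);
    for (int v = 0; v < V; ++v) {
      double t = 0.0;
      if (inmask[v] && ctgc > 0.0) {
        const double sc = std::max(yty(v), 1.0);
        const double rss = std::max(yty(v) - quad(v), 0.0);
        const double sigma2 = rss / df;
        if (sigma2 > 1e-12 * sc / df)
          t = num(v) / std::sqrt(sigma2 * ctgc);
        else if (std::abs(num(v)) > 1e-12 * std::sqrt(sc))
          t = num(v) > 0 ? R_PosInf : R_NegInf;
      }
      tvec(v) = t;
    }
    smooth_inplace(tvec, K1, K2, K3, W, d1, d2, d3);
    out.col(b) = tvec;
  }
  return out;
}

// Across-subject voxelwise median for each run, returning the in-mask
// extrema: a B x 2 matrix (max, min). `maps` is a list of V x B matrices,
// one per subject. Even subject counts take the midpoint of the two
// central order statistics.
// [[Rcpp::export]]
arma::mat cpp_median_extrema(const Rcpp::List &maps,
                             const arma::uvec &mask0) {
  const int S = maps.size();
  std::vector<Rcpp::NumericMatrix> M(S);
  for (int s = 0; s < S; ++s) M[s] = Rcpp::as<Rcpp::NumericMatrix>(maps[s]);
  const int V = M[0].nrow();
  const int B = M[0].ncol();
  mat out(B, 2);
  std::vector<double> buf(S);
  const int k2 = S / 2;         // upper middle (0-based)
  const int k1 = (S - 1) / 2;   // lower middle
  for (int b = 0; b < B; ++b) {
    double mx = -datum::inf, mn = datum::inf;
    const int off = b * V;
    for (uword mi = 0; mi < mask0.n_elem; ++mi) {
      const int v = mask0(mi);
      for (int s = 0; s < S; ++s) buf[s] = M[s][off + v];
      std::nth_element(buf.begin(), buf.begin() + k1, buf.end());
      double med = buf[k1];
      if (k2 != k1) {
        const double hi =
            *std::min_element(buf.begin() + k1 + 1, buf.end());
        med = 0.5 * (med + hi);
      }
      if (med > mx) mx = med;
      if (med < mn) mn = med;
    }
    out(b, 0) = mx;
    out(b, 1) = mn;
  }
  return out;
}
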