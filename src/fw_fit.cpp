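// Hot paths of the IDEAL-type variable-projection fat-water estimator.
// The model per voxel is y(t) = W a1(t) + F a2(t) with
//   a1(t) = exp((i 2 pi f0 - R2*) t),  a2(t) = c(t) a1(t),
// c(t) the net fat phasor of the spectrum. For fixed (f0, R2*) the complex
// amplitudes solve a 2-column linear least squares; the residual landscape
// over (f0, R2*) is explored by a shared coarse grid (BLAS gemm over all
// voxels at once) followed by per-voxel local grid refinement.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::uword;

// Coarse grid search. Y is (ne x N) voxel signals; B is (ne x 2C) with
// columns 2c-1, 2c holding an orthonormal basis pair for candidate c.
// Returns, per voxel, the candidate index maximizing the projected energy
// |Q^H y|^2 (equivalently minimizing the residual norm).
// [[Rcpp::export]]
List cpp_coarse_search(const arma::cx_mat& Y, const arma::cx_mat& B) {
  const uword N = Y.n_cols;
  const uword C = B.n_cols / 2;
  std::vector<double> best(N, -1.0);
  std::vector<int> besti(N, 1);
  const uword cblk = 128, nblk = 4096;
  for (uword n0 = 0; n0 < N; n0 += nblk) {
    const uword n1 = std::min(n0 + nblk, N) - 1;
    const arma::cx_mat Yc = Y.cols(n0, n1);
    const uword nc = Yc.n_cols;
    for (uword c0 = 0; c0 < C; c0 += cblk) {
      const uword c1 = std::min(c0 + cblk, C) - 1;
      // Hermitian-transpose gemm: (2b x ne) * (ne x nc)
      const arma::cx_mat P = B.cols(2 * c0, 2 * c1 + 1).t() * Yc;
      for (uword c = c0; c <= c1; ++c) {
        const uword r0 = 2 * (c - c0);
        for (uword j = 0; j < nc; ++j) {
          const double p = std::norm(P(r0, j)) + std::norm(P(r0 + 1, j));
          if (p > best[n0 + j]) {
            best[n0 + j] = p;
            besti[n0 + j] = (int)c + 1;
          }
        }
      }
    }
  }
  return List::create(_["index"] = wrap(besti), _["proj2"] = wrap(best));
}

// Residual of the projected least-squares problem at one (f0, r2s) for one
// voxel, via the closed-form 2x2 Hermitian normal equations. Returns the
// residual norm^2 and fills W, F.
static inline double eval_candidate(const arma::cx_vec& y, const arma::vec& te,
                                    const arma::cx_vec& ct, double f0,
                                    double r2s, double ynorm2,
                                    std::complex<double>& W,
                                    std::complex<double>& F) {
  const uword ne = te.n_elem;
  double g11 = 0.0, g22 = 0.0;
  std::complex<double> g12(0.0, 0.0), b1(0.0, 0.0), b2(0.0, 0.0);
  for (uword e = 0; e < ne; ++e) {
    const double d = std::exp(-2.0 * r2s * te[e]);
    const double ph = 2.0 * M_PI * f0 * te[e];
    const std::complex<double> a1(std::cos(ph) * std::exp(-r2s * te[e]),
                                  std::sin(ph) * std::exp(-r2s * te[e]));
    const std::complex<double> c = ct[e];
    g11 += d;
    g22 += std::norm(c) * d;
    g12 += c * d;
    const std::complex<double> cya1 = std::conj(a1) * y[e];
    b1 += cya1;
    b2 += std::conj(c) * cya1;
  }
  const double det = g11 * g22 - std::norm(g12);
  if (det > 1e-12 * g11 * g22 && det > 0.0) {
    W = (g22 * b1 - g12 * b2) / det;
    F = (g11 * b2 - std::conj(g12) * b1) / det;
  } else {  // degenerate basis (fat phasor constant): rank-1 fallback
    W = b1 / g11;
    F = std::complex<double>(0.0, 0.0);
  }
  const double proj2 = std::real(std::conj(b1) * W + std::conj(b2) * F);
  return ynorm2 - proj2;
}

// Per-voxel local refinement: successive 5x5 grid zooms over (f0, r2s)
// starting from the provided centers with initial half-spans span/2,
// halving the span each round. n_rounds = 0 only evaluates the center
// (used to finalize amplitudes at fixed parameters). R2* is clamped to
// [r2s_min, r2s_max]; f0 is clamped per voxel to [f0_lo, f0_hi] so a
// constrained refit cannot wander back into an excluded (swapped) basin.
// [[Rcpp::export]]
List cpp_refine(const arma::cx_mat& Y, const arma::vec& te,
                const arma::cx_vec& ct, const arma::vec& f0_init,
                const arma::vec& r2s_init, double span_f0, double span_r2s,
                int n_rounds, double r2s_min, double r2s_max,
                const arma::vec& f0_lo, const arma::vec& f0_hi) {
  const uword N = Y.n_cols;
  arma::vec f0_out(N), r2s_out(N), res_out(N);
  arma::cx_vec W_out(N), F_out(N);
  for (uword v = 0; v < N; ++v) {
    const arma::cx_vec y = Y.col(v);
    const double ynorm2 = std::real(arma::cdot(y, y));
    const double flo = f0_lo.n_elem == 1 ? f0_lo[0] : f0_lo[v];
    const double fhi = f0_hi.n_elem == 1 ? f0_hi[0] : f0_hi[v];
    double f0 = std::min(std::max(f0_init[v], flo), fhi);
    double r2s = std::min(std::max(r2s_init[v], r2s_min), r2s_max);
    std::complex<double> W, F;
    double best = eval_candidate(y, te, ct, f0, r2s, ynorm2, W, F);
    std::complex<double> Wb = W, Fb = F;
    double sf = span_f0, sr = span_r2s;
    for (int round = 0; round < n_rounds; ++round) {
      double f0c = f0, r2c = r2s;
      for (int i = -2; i <= 2; ++i) {
        for (int j = -2; j <= 2; ++j) {
          if (i == 0 && j == 0) continue;
          double f0t = f0c + i * sf / 4.0;
          f0t = std::min(std::max(f0t, flo), fhi);
          double r2t = r2c + j * sr / 4.0;
          r2t = std::min(std::max(r2t, r2s_min), r2s_max);
          const double r = eval_candidate(y, te, ct, f0t, r2t, ynorm2, W, F);
          if (r < best) {
            best = r;
            f0 = f0t;
            r2s = r2t;
            Wb = W;
            Fb = F;
          }
        }
      }
      sf /= 2.0;
      sr /= 2.0;
    }
    f0_out[v] = f0;
    r2s_out[v] = r2s;
    res_out[v] = std::max(best, 0.0);
    W_out[v] = Wb;
    F_out[v] = Fb;
  }
  return List::create(_["f0"] = f0_out, _["r2s"] = r2s_out,
                      _["W"] = W_out, _["F"] = F_out,
                      _["resnorm"] = res_out);
}

// 3x3x3 median filter with replicate padding at the edges; used by the
// spatially constrained field-map regularization.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(x.size());
  std::vector<double> buf(27);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int n = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          const int kk = std::min(std::max(k + dk, 0), nz - 1);
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = std::min(std::max(j + dj, 0), ny - 1);
            for (int di = -1; di <= 1; ++di) {
              const int ii = std::min(std::max(i + di, 0), nx - 1);
              buf[n++] = x[ii + nx * (jj + ny * kk)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + 13, buf.begin() + 27);
        out[i + nx * (j + ny * k)] = buf[13];
      }
    }
  }
  return out;
}
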