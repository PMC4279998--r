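#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Per-voxel eigendecomposition of a symmetric 3x3 Hessian field.
// Eigenvalues come back in ascending signed order (arma::eig_sym's order),
// which is the ordering the linear-structure measure's branch conditions
// assume. Only e3 (eigenvector of the largest eigenvalue, i.e. the tube
// axis direction for bright tubes) is returned alongside the eigenvalues.
// [[Rcpp::export]]
List hessian_eigen_cpp(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                       NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  R_xlen_t n = hxx.size();
  NumericMatrix evals(n, 3);
  NumericMatrix e3(n, 3);
  arma::mat33 H;
  arma::vec ev;
  arma::mat V;
  for (R_xlen_t i = 0; i < n; ++i) {
    H(0, 0) = hxx[i]; H(1, 1) = hyy[i]; H(2, 2) = hzz[i];
    H(0, 1) = H(1, 0) = hxy[i];
    H(0, 2) = H(2, 0) = hxz[i];
    H(1, 2) = H(2, 1) = hyz[i];
    if (!arma::eig_sym(ev, V, H))
      stop("eigendecomposition failed at voxel %td", (ptrdiff_t)(i + 1));
    evals(i, 0) = ev[0]; evals(i, 1) = ev[1]; evals(i, 2) = ev[2];
    e3(i, 0) = V(0, 2); e3(i, 1) = V(1, 2); e3(i, 2) = V(2, 2);
  }
  return List::create(_["values"] = evals, _["e3"] = e3);
}

// 3D median filter with replicate (clamp-to-edge) boundary handling.
// Window is the full (2r+1)^3 cube; the median of an odd count is the
// middle order statistic.
// [[Rcpp::export]]
NumericVector median_filter_cpp(NumericVector x, IntegerVector dims, int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(x.size());
  std::vector<double> buf;
  const int k = 2 * radius + 1;
  buf.reserve((size_t)k * k * k);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int xi = 0; xi < nx; ++xi) {
        buf.clear();
        for (int dz = -radius; dz <= radius; ++dz) {
          const int zz = std::min(std::max(z + dz, 0), nz - 1);
          for (int dy = -radius; dy <= radius; ++dy) {
            const int yy = std::min(std::max(y + dy, 0), ny - 1);
            const R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            for (int dx = -radius; dx <= radius; ++dx) {
              const int xx = std::min(std::max(xi + dx, 0), nx - 1);
              buf.push_back(x[base + xx]);
            }
          }
        }
        const size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out[xi + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = buf[m];
      }
    }
  }
  return out;
}
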