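// Parallel-beam Radon transform and (filtered) backprojection.
// Geometry: 0-based (row, col) pixel coordinates, pixel centers at integers,
// rotation centre at ((H-1)/2, (W-1)/2). Detector axis t spans the image
// diagonal (odd number of unit-spaced bins, bin (ndet-1)/2 at t = 0).
// A line at angle theta is x = t cos(theta) - s sin(theta),
//                          y = t sin(theta) + s cos(theta)  (s = arc length).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double bilin(const mat& img, double y, double x) {
  const int h = img.n_rows, w = img.n_cols;
  if (y <= -1.0 || x <= -1.0 || y >= (double)h || x >= (double)w) return 0.0;
  const int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  const double fy = y - y0, fx = x - x0;
  double v = 0.0;
  for (int dy = 0; dy < 2; ++dy) {
    const int yy = y0 + dy;
    if (yy < 0 || yy >= h) continue;
    const double wy = dy ? fy : 1.0 - fy;
    if (wy == 0.0) continue;
    for (int dx = 0; dx < 2; ++dx) {
      const int xx = x0 + dx;
      if (xx < 0 || xx >= w) continue;
      const double wx = dx ? fx : 1.0 - fx;
      v += wy * wx * img(yy, xx);
    }
  }
  return v;
}

// [[Rcpp::export]]
int cpp_detector_bins(int h, int w) {
  const double diag = std::sqrt((double)h * h + (double)w * w);
  int ndet = (int)std::ceil(diag);
  if (ndet % 2 == 0) ndet += 1;
  return ndet;
}

// [[Rcpp::export]]
arma::mat cpp_radon(const arma::mat& img, const arma::vec& theta_deg,
                    const int s_substeps = 2) {
  const int h = img.n_rows, w = img.n_cols;
  const int na = theta_deg.n_elem;
  const int ndet = cpp_detector_bins(h, w);
  const double c = (ndet - 1) / 2.0;
  const double cy = (h - 1) / 2.0, cx = (w - 1) / 2.0;
  const int ns = (ndet - 1) * s_substeps + 1;
  const double ds = 1.0 / s_substeps;
  mat sino(ndet, na, fill::zeros);
  for (int a = 0; a < na; ++a) {
    const double th = theta_deg[a] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    for (int i = 0; i < ndet; ++i) {
      const double t = i - c;
      double acc = 0.0;
      for (int k = 0; k < ns; ++k) {
        const double s = -c + k * ds;
        const double x = cx + t * ct - s * st;
        const double y = cy + t * st + s * ct;
        acc += bilin(img, y, x);
      }
      sino(i, a) = acc * ds;
    }
  }
  return sino;
}

// Backprojection of (already filtered) projections onto an H x W grid,
// scaled by pi / n_angles so intensities are comparable across angle sets.
// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& sino, const arma::vec& theta_deg,
                          const int h, const int w) {
  const int ndet = sino.n_rows;
  const int na = theta_deg.n_elem;
  const double c = (ndet - 1) / 2.0;
  const double cy = (h - 1) / 2.0, cx = (w - 1) / 2.0;
  mat out(h, w, fill::zeros);
  for (int a = 0; a < na; ++a) {
    const double th = theta_deg[a] * M_PI / 180.0;
    const double ct = std::cos(th), st = std::sin(th);
    const double* col = sino.colptr(a);
    for (int x = 0; x < w; ++x) {
      const double xc = (x - cx) * ct;
      for (int y = 0; y < h; ++y) {
        const double t = xc + (y - cy) * st + c;
        const int t0 = (int)std::floor(t);
        const double f = t - t0;
        double v = 0.0;
        if (t0 >= 0 && t0 < ndet) v += (1.0 - f) * col[t0];
        if (t0 + 1 >= 0 && t0 + 1 < ndet) v += f * col[t0 + 1];
        out(y, x) += v;
      }
    }
  }
  out *= M_PI / na;
  return out;
}

// Connected-component labeling of a binary mask (4- or 8-connectivity).
// Returns an integer matrix with 0 = background, components numbered 1..n
// in raster order of their first-encountered pixel.
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_label_components(const Rcpp::IntegerMatrix& mask,
                                         const int connectivity = 8) {
  const int h = mask.nrow(), w = mask.ncol();
  Rcpp::IntegerMatrix lab(h, w);
  const int n_off = (connectivity == 8) ? 8 : 4;
  const int offy[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int offx[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      stack.clear();
      stack.emplace_back(y, x);
      lab(y, x) = next;
      while (!stack.empty()) {
        auto [cy_, cx_] = stack.back();
        stack.pop_back();
        for (int k = 0; k < n_off; ++k) {
          const int ny = cy_ + offy[k], nx = cx_ + offx[k];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.emplace_back(ny, nx);
          }
        }
      }
    }
  }
  return lab;
}
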