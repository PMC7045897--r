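// Image resampling: 2D linear / nearest-neighbour resampling on a scaled
// grid (in-plane downsampling and augmentation zoom), and 3D resampling of
// a volume under a rigid/affine physical-space transform (registration).

#include <RcppArmadillo.h>
using namespace arma;

// Sample img at continuous (0-based) index positions
//   u = off_r + scale_r * i,  v = off_c + scale_c * j
// for output pixel (i, j); bilinear with edge clamping.
// [[Rcpp::export(name = ".cpp_resample2d")]]
arma::mat cpp_resample2d(const arma::mat& img, int out_r, int out_c,
                         double scale_r, double scale_c,
                         double off_r, double off_c, bool nearest) {
  const int H = img.n_rows, W = img.n_cols;
  mat out(out_r, out_c);
  for (int j = 0; j < out_c; ++j) {
    double v = off_c + scale_c * j;
    for (int i = 0; i < out_r; ++i) {
      double u = off_r + scale_r * i;
      if (nearest) {
        int iu = (int)std::lround(u), iv = (int)std::lround(v);
        iu = std::min(std::max(iu, 0), H - 1);
        iv = std::min(std::max(iv, 0), W - 1);
        out(i, j) = img(iu, iv);
      } else {
        double uc = std::min(std::max(u, 0.0), (double)(H - 1));
        double vc = std::min(std::max(v, 0.0), (double)(W - 1));
        int u0 = (int)std::floor(uc), v0 = (int)std::floor(vc);
        int u1 = std::min(u0 + 1, H - 1), v1 = std::min(v0 + 1, W - 1);
        double fu = uc - u0, fv = vc - v0;
        out(i, j) = (1 - fu) * (1 - fv) * img(u0, v0)
                  + fu * (1 - fv) * img(u1, v0)
                  + (1 - fu) * fv * img(u0, v1)
                  + fu * fv * img(u1, v1);
      }
    }
  }
  return out;
}

// Resample `moving` onto the fixed grid under the physical-space map
//   q = A * (p - center) + center + t
// where p is the physical position of a fixed voxel; the moving volume is
// interpolated trilinearly at q. Voxels mapping outside the moving volume
// are set to `fill` (use NaN to mark them invalid for metric evaluation).
// [[Rcpp::export(name = ".cpp_resample3d_affine")]]
arma::cube cpp_resample3d_affine(const arma::cube& moving,
                                 const arma::vec& msp, const arma::vec& morg,
                                 int fd1, int fd2, int fd3,
                                 const arma::vec& fsp, const arma::vec& forg,
                                 const arma::mat& A, const arma::vec& t,
                                 const arma::vec& center,
                                 double fill, bool nearest) {
  const int H = moving.n_rows, W = moving.n_cols, D = moving.n_slices;
  cube out(fd1, fd2, fd3);
  vec p(3), q(3);
  for (int k = 0; k < fd3; ++k) {
    p(2) = forg(2) + fsp(2) * k;
    for (int j = 0; j < fd2; ++j) {
      p(1) = forg(1) + fsp(1) * j;
      for (int i = 0; i < fd1; ++i) {
        p(0) = forg(0) + fsp(0) * i;
        q = A * (p - center) + center + t;
        double u = (q(0) - morg(0)) / msp(0);
        double v = (q(1) - morg(1)) / msp(1);
        double w = (q(2) - morg(2)) / msp(2);
        if (u < 0 || u > H - 1 || v < 0 || v > W - 1 || w < 0 || w > D - 1) {
          out(i, j, k) = fill;
          continue;
        }
        if (nearest) {
          out(i, j, k) = moving((int)std::lround(u), (int)std::lround(v),
                                (int)std::lround(w));
          continue;
        }
        int u0 = (int)std::floor(u), v0 = (int)std::floor(v),
            w0 = (int)std::floor(w);
        int u1 = std::min(u0 + 1, H - 1), v1 = std::min(v0 + 1, W - 1),
            w1 = std::min(w0 + 1, D - 1);
        double fu = u - u0, fv = v - v0, fw = w - w0;
        double c00 = (1 - fu) * moving(u0, v0, w0) + fu * moving(u1, v0, w0);
        double c10 = (1 - fu) * moving(u0, v1, w0) + fu * moving(u1, v1, w0);
        double c01 = (1 - fu) * moving(u0, v0, w1) + fu * moving(u1, v0, w1);
        double c11 = (1 - fu) * moving(u0, v1, w1) + fu * moving(u1, v1, w1);
        double c0 = (1 - fv) * c00 + fv * c10;
        double c1 = (1 - fv) * c01 + fv * c11;
        out(i, j, k) = (1 - fw) * c0 + fw * c1;
      }
    }
  }
  return out;
}

// Mutual information between two equally shaped volumes from a joint
// histogram with `bins` equal-width bins per axis; voxels where either
// volume is NaN are skipped. Returns -1e9 when fewer than 10 voxels overlap.
// [[Rcpp::export(name = ".cpp_mutual_information")]]
double cpp_mutual_information(const arma::cube& a, const arma::cube& b,
                              int bins) {
  const uword n = a.n_elem;
  double amin = datum::inf, amax = -datum::inf;
  double bmin = datum::inf, bmax = -datum::inf;
  uword nv = 0;
  for (uword i = 0; i < n; ++i) {
    double x = a(i), y = b(i);
    if (std::isnan(x) || std::isnan(y)) continue;
    ++nv;
    if (x < amin) amin = x; if (x > amax) amax = x;
    if (y < bmin) bmin = y; if (y > bmax) bmax = y;
  }
  if (nv < 10) return -1e9;
  double ar = amax - amin, br = bmax - bmin;
  if (ar <= 0) ar = 1; if (br <= 0) br = 1;
  mat joint(bins, bins, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double x = a(i), y = b(i);
    if (std::isnan(x) || std::isnan(y)) continue;
    int bi = (int)((x - amin) / ar * bins);
    int bj = (int)((y - bmin) / br * bins);
    if (bi >= bins) bi = bins - 1;
    if (bj >= bins) bj = bins - 1;
    joint(bi, bj) += 1.0;
  }
  joint /= (double)nv;
  vec pa = sum(joint, 1);
  rowvec pb = sum(joint, 0);
  double mi = 0;
  for (int i = 0; i < bins; ++i) {
    if (pa(i) <= 0) continue;
    for (int j = 0; j < bins; ++j) {
      double p = joint(i, j);
      if (p <= 0 || pb(j) <= 0) continue;
      mi += p * std::log(p / (pa(i) * pb(j)));
    }
  }
  return mi;
}
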