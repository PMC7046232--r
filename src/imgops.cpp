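// Low-level image kernels: interpolation, warping, mutual information,
// Gaussian smoothing, displacement-field algebra.
//
// Conventions (shared with the R layer):
//  - images are numeric matrices; row index = anterior-posterior axis (x),
//    column index = medial-lateral axis (y); toe at high row index
//  - physical coordinate of pixel (i, j) (0-based here) is (i*sp, j*sp) mm
//    on the common isotropic grid
//  - a rigid transform maps FIXED-grid physical points p to MOVING-image
//    points: T(p) = R(theta) (p - c) + c + t
//  - a displacement field u lives on the fixed grid (mm); warping samples
//    the moving image at T(p + u(p))
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double px_at(const NumericMatrix& img, int i, int j) {
  if (i < 0 || j < 0 || i >= img.nrow() || j >= img.ncol()) return 0.0;
  return img(i, j);
}

static inline double px_clamped(const NumericMatrix& img, int i, int j) {
  if (i < 0) i = 0;
  if (j < 0) j = 0;
  if (i >= img.nrow()) i = img.nrow() - 1;
  if (j >= img.ncol()) j = img.ncol() - 1;
  return img(i, j);
}

// Catmull-Rom cubic kernel weights for fractional offset t in [0,1)
static inline void cubic_w(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2.0 * t2 - t);
  w[1] = 0.5 * (3.0 * t3 - 5.0 * t2 + 2.0);
  w[2] = 0.5 * (-3.0 * t3 + 4.0 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

// interp: 0 = nearest, 1 = bilinear, 3 = bicubic. Outside the image the
// value is 0 (warping) or the border value (replicate = true, resampling).
static double sample_img(const NumericMatrix& img, double fi, double fj,
                         int interp, bool replicate = false) {
  int nr = img.nrow(), nc = img.ncol();
  if (interp == 0) {
    int i = (int)std::lround(fi), j = (int)std::lround(fj);
    return replicate ? px_clamped(img, i, j) : px_at(img, i, j);
  }
  if (!replicate && (fi < -1.0 || fj < -1.0 || fi > (double)nr || fj > (double)nc))
    return 0.0;
  int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj);
  double ti = fi - i0, tj = fj - j0;
  if (interp == 1) {
    double v00, v01, v10, v11;
    if (replicate) {
      v00 = px_clamped(img, i0, j0);     v01 = px_clamped(img, i0, j0 + 1);
      v10 = px_clamped(img, i0 + 1, j0); v11 = px_clamped(img, i0 + 1, j0 + 1);
    } else {
      v00 = px_at(img, i0, j0);     v01 = px_at(img, i0, j0 + 1);
      v10 = px_at(img, i0 + 1, j0); v11 = px_at(img, i0 + 1, j0 + 1);
    }
    return (1 - ti) * ((1 - tj) * v00 + tj * v01) + ti * ((1 - tj) * v10 + tj * v11);
  }
  double wi[4], wj[4];
  cubic_w(ti, wi);
  cubic_w(tj, wj);
  double acc = 0.0;
  for (int a = 0; a < 4; ++a) {
    int ia = i0 - 1 + a;
    if (wi[a] == 0.0) continue;
    double row = 0.0;
    for (int b = 0; b < 4; ++b) {
      int jb = j0 - 1 + b;
      row += wj[b] * (replicate ? px_clamped(img, ia, jb) : px_at(img, ia, jb));
    }
    acc += wi[a] * row;
  }
  return acc;
}

// [[Rcpp::export]]
NumericMatrix cpp_resample(NumericMatrix img, double sx, double sy,
                           double out_sp, int interp, bool clamp_neg) {
  int nr = img.nrow(), nc = img.ncol();
  int onr = std::max(1, (int)std::lround(nr * sx / out_sp));
  int onc = std::max(1, (int)std::lround(nc * sy / out_sp));
  NumericMatrix out(onr, onc);
  // border replication so the resampled grid covers the full physical
  // extent without edge decay (and constants stay constant)
  for (int j = 0; j < onc; ++j) {
    double fj = j * out_sp / sy;
    for (int i = 0; i < onr; ++i) {
      double fi = i * out_sp / sx;
      double v = sample_img(img, fi, fj, interp, true);
      if (clamp_neg && v < 0.0) v = 0.0;
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp(NumericMatrix img, int out_nr, int out_nc,
                       double theta, double tx, double ty,
                       double cx, double cy,
                       Nullable<NumericMatrix> ux_, Nullable<NumericMatrix> uy_,
                       double sp, int interp, bool clamp_neg) {
  NumericMatrix out(out_nr, out_nc);
  bool has_field = ux_.isNotNull();
  NumericMatrix ux, uy;
  if (has_field) { ux = NumericMatrix(ux_); uy = NumericMatrix(uy_); }
  double ct = std::cos(theta), st = std::sin(theta);
  for (int j = 0; j < out_nc; ++j) {
    for (int i = 0; i < out_nr; ++i) {
      double px = i * sp, py = j * sp;
      if (has_field) { px += ux(i, j); py += uy(i, j); }
      double dx = px - cx, dy = py - cy;
      double qx = ct * dx - st * dy + cx + tx;
      double qy = st * dx + ct * dy + cy + ty;
      double v = sample_img(img, qx / sp, qy / sp, interp);
      if (clamp_neg && v < 0.0) v = 0.0;
      out(i, j) = v;
    }
  }
  return out;
}

// Histogram-based mutual information (nats) over pixels where either image
// is positive; per-image intensity range [0, max].
// [[Rcpp::export]]
double cpp_mi(NumericMatrix a, NumericMatrix b, int bins) {
  int n = a.nrow() * a.ncol();
  double amax = 0.0, bmax = 0.0;
  for (int k = 0; k < n; ++k) {
    if (a[k] > amax) amax = a[k];
    if (b[k] > bmax) bmax = b[k];
  }
  if (amax <= 0.0 || bmax <= 0.0) return 0.0;
  std::vector<double> joint(bins * bins, 0.0), pa(bins, 0.0), pb(bins, 0.0);
  double total = 0.0;
  for (int k = 0; k < n; ++k) {
    if (a[k] <= 0.0 && b[k] <= 0.0) continue;
    int ia = (int)(a[k] / amax * bins);
    int ib = (int)(b[k] / bmax * bins);
    if (ia >= bins) ia = bins - 1;
    if (ib >= bins) ib = bins - 1;
    if (ia < 0) ia = 0;
    if (ib < 0) ib = 0;
    joint[ia * bins + ib] += 1.0;
    total += 1.0;
  }
  if (total <= 0.0) return 0.0;
  for (int ia = 0; ia < bins; ++ia)
    for (int ib = 0; ib < bins; ++ib) {
      double p = joint[ia * bins + ib] / total;
      joint[ia * bins + ib] = p;
      pa[ia] += p;
      pb[ib] += p;
    }
  double mi = 0.0;
  for (int ia = 0; ia < bins; ++ia) {
    if (pa[ia] <= 0.0) continue;
    for (int ib = 0; ib < bins; ++ib) {
      double p = joint[ia * bins + ib];
      if (p > 0.0 && pb[ib] > 0.0) mi += p * std::log(p / (pa[ia] * pb[ib]));
    }
  }
  return mi < 0.0 ? 0.0 : mi;
}

// Separable Gaussian smoothing, reflected borders.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_smooth(NumericMatrix m, double sigma) {
  int nr = m.nrow(), nc = m.ncol();
  if (sigma <= 0.0) return clone(m);
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int d = -rad; d <= rad; ++d) {
    k[d + rad] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += k[d + rad];
  }
  for (auto& v : k) v /= s;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d) acc += k[d + rad] * m(reflect(i + d, nr), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -rad; d <= rad; ++d) acc += k[d + rad] * tmp(i, reflect(j + d, nc));
      out(i, j) = acc;
    }
  return out;
}

// Bilinear sampling of a displacement component with edge clamping (fields
// are extended by their border values rather than zero, so composed points
// just outside the lattice keep a sensible displacement).
static double sample_field(const NumericMatrix& u, double fi, double fj) {
  int nr = u.nrow(), nc = u.ncol();
  if (fi < 0) fi = 0;
  if (fj < 0) fj = 0;
  if (fi > nr - 1) fi = nr - 1;
  if (fj > nc - 1) fj = nc - 1;
  int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj);
  int i1 = std::min(i0 + 1, nr - 1), j1 = std::min(j0 + 1, nc - 1);
  double ti = fi - i0, tj = fj - j0;
  return (1 - ti) * ((1 - tj) * u(i0, j0) + tj * u(i0, j1)) +
         ti * ((1 - tj) * u(i1, j0) + tj * u(i1, j1));
}

// Composition (u_a followed by u_b as point maps): result(x) = u_a(x) + u_b(x + u_a(x)).
// [[Rcpp::export]]
List cpp_compose_field(NumericMatrix uxa, NumericMatrix uya,
                       NumericMatrix uxb, NumericMatrix uyb, double sp) {
  int nr = uxa.nrow(), nc = uxa.ncol();
  NumericMatrix ox(nr, nc), oy(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double fi = i + uxa(i, j) / sp, fj = j + uya(i, j) / sp;
      ox(i, j) = uxa(i, j) + sample_field(uxb, fi, fj);
      oy(i, j) = uya(i, j) + sample_field(uyb, fi, fj);
    }
  return List::create(_["ux"] = ox, _["uy"] = oy);
}

// Jacobian determinant of x + u(x), central differences (one-sided at edges).
// [[Rcpp::export]]
NumericMatrix cpp_jacobian(NumericMatrix ux, NumericMatrix uy, double sp) {
  int nr = ux.nrow(), nc = ux.ncol();
  NumericMatrix J(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int im = std::max(i - 1, 0), ip = std::min(i + 1, nr - 1);
      int jm = std::max(j - 1, 0), jp = std::min(j + 1, nc - 1);
      double hx = (ip - im) * sp, hy = (jp - jm) * sp;
      double dux_dx = (ux(ip, j) - ux(im, j)) / hx;
      double dux_dy = (ux(i, jp) - ux(i, jm)) / hy;
      double duy_dx = (uy(ip, j) - uy(im, j)) / hx;
      double duy_dy = (uy(i, jp) - uy(i, jm)) / hy;
      J(i, j) = (1.0 + dux_dx) * (1.0 + duy_dy) - dux_dy * duy_dx;
    }
  return J;
}

// Thirion demons force toward the fixed image; the k2 term (mean squared
// spacing) normalizes the step so displacements come out in mm.
// [[Rcpp::export]]
List cpp_demons_force(NumericMatrix fixed, NumericMatrix warped, double sp,
                      double k2, double eps) {
  int nr = fixed.nrow(), nc = fixed.ncol();
  NumericMatrix vx(nr, nc), vy(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int im = std::max(i - 1, 0), ip = std::min(i + 1, nr - 1);
      int jm = std::max(j - 1, 0), jp = std::min(j + 1, nc - 1);
      // symmetric (ESM-style) gradient: average of fixed and warped-moving
      double gx = 0.5 * ((warped(ip, j) - warped(im, j)) +
                         (fixed(ip, j) - fixed(im, j))) / ((ip - im) * sp);
      double gy = 0.5 * ((warped(i, jp) - warped(i, jm)) +
                         (fixed(i, jp) - fixed(i, jm))) / ((jp - jm) * sp);
      double diff = fixed(i, j) - warped(i, j);
      double denom = gx * gx + gy * gy + diff * diff / k2 + eps;
      if (denom > 0.0) {
        vx(i, j) = diff * gx / denom;
        vy(i, j) = diff * gy / denom;
      }
    }
  return List::create(_["ux"] = vx, _["uy"] = vy);
}

// Full (1+1) evolution strategy for rigid MI registration: mutation loop,
// warping and histogram MI all in C++ (uses R's RNG so runs are seeded).
// [[Rcpp::export]]
List cpp_es_rigid(NumericMatrix moving, NumericMatrix fixed,
                  double cx, double cy, double sp,
                  NumericVector p0, NumericVector sig0,
                  double grow, double shrink, int max_iter,
                  NumericVector min_step, int bins) {
  int nr = fixed.nrow(), nc = fixed.ncol();
  NumericMatrix buf(nr, nc);
  auto score = [&](double th, double tx, double ty) {
    double ct = std::cos(th), st = std::sin(th);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double dx = i * sp - cx, dy = j * sp - cy;
        double qx = ct * dx - st * dy + cx + tx;
        double qy = st * dx + ct * dy + cy + ty;
        buf(i, j) = sample_img(moving, qx / sp, qy / sp, 1);
      }
    return cpp_mi(fixed, buf, bins);
  };
  double p[3] = {p0[0], p0[1], p0[2]};
  double sig[3] = {sig0[0], sig0[1], sig0[2]};
  double s = score(p[0], p[1], p[2]);
  std::vector<double> trace;
  trace.push_back(s);
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    NumericVector eps = rnorm(3);
    double cand[3] = {p[0] + sig[0] * eps[0], p[1] + sig[1] * eps[1],
                      p[2] + sig[2] * eps[2]};
    double sc = score(cand[0], cand[1], cand[2]);
    if (sc > s) {
      p[0] = cand[0]; p[1] = cand[1]; p[2] = cand[2];
      s = sc;
      trace.push_back(sc);
      for (int k = 0; k < 3; ++k) sig[k] *= grow;
    } else {
      for (int k = 0; k < 3; ++k) sig[k] *= shrink;
    }
    if (sig[0] < min_step[0] && sig[1] < min_step[1]) {
      converged = true;
      break;
    }
  }
  return List::create(_["p"] = NumericVector::create(p[0], p[1], p[2]),
                      _["score"] = s, _["trace"] = wrap(trace),
                      _["converged"] = converged);
}
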