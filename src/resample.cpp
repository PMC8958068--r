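// Separable-kernel 3D resampling on regular grids.
//
// All kernels operate in the input index space of each axis; per-axis tap
// weights are normalised to sum to one so that every kernel reproduces a
// constant image exactly. Out-of-support taps are clamped to the nearest
// edge sample.
#include <Rcpp.h>
#include <map>
#include <cmath>
using namespace Rcpp;

static inline double sinc(double x) {
  if (std::fabs(x) < 1e-12) return 1.0;
  double px = M_PI * x;
  return std::sin(px) / px;
}

// windowed-sinc windows, argument d in voxels, window radius m
static double window_fun(const std::string& kern, double d, double m) {
  if (kern == "BL") return 0.42 + 0.50 * std::cos(M_PI * d / m) + 0.08 * std::cos(2.0 * M_PI * d / m);
  if (kern == "CWS") return std::cos(M_PI * d / (2.0 * m));
  if (kern == "HWS") return 0.54 + 0.46 * std::cos(M_PI * d / m);
  if (kern == "LWS") return sinc(d / m);
  if (kern == "WWS") return 1.0 - (d / m) * (d / m);
  stop("unknown windowed-sinc kernel");
  return 0.0;
}

// cubic B-spline prefilter along a contiguous line (Unser et al.),
// pole z1 = sqrt(3) - 2, mirror (reflective) boundary
static void bspline_prefilter_line(std::vector<double>& c) {
  const int n = (int)c.size();
  if (n == 1) return;
  const double z = std::sqrt(3.0) - 2.0;
  const double lambda = 6.0;
  for (int i = 0; i < n; ++i) c[i] *= lambda;
  // causal init with mirror boundary: geometric sum, exact for short lines
  int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z)));
  double sum;
  if (horizon < n) {
    sum = c[0];
    double zk = z;
    for (int k = 1; k < horizon; ++k) { sum += zk * c[k]; zk *= z; }
  } else {
    double zn = z, iz = 1.0 / z;
    double z2n = std::pow(z, n - 1);
    sum = c[0] + z2n * c[n - 1];
    z2n *= z2n * iz;
    for (int k = 1; k <= n - 2; ++k) { sum += (zn + z2n) * c[k]; zn *= z; z2n *= iz; }
    sum /= 1.0 - std::pow(z, 2 * n - 2);
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i] += z * c[i - 1];
  // anticausal init
  c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
  for (int i = n - 2; i >= 0; --i) c[i] = z * (c[i + 1] - c[i]);
}

struct AxisTaps {
  // for each output index along one axis: first input tap and weights
  std::vector<int> start;
  std::vector<std::vector<double> > w;
};

// continuous input index of output sample i along an axis
static inline double map_index(int i, double out_orig, double out_sp,
                               double in_orig, double in_sp) {
  return (out_orig + i * out_sp - in_orig) / in_sp;
}

static AxisTaps make_axis_taps(int n_out, int n_in, double out_orig, double out_sp,
                               double in_orig, double in_sp,
                               const std::string& kern, double sigma_mm) {
  AxisTaps at;
  at.start.resize(n_out);
  at.w.resize(n_out);
  const double m = 3.0; // windowed-sinc radius (voxels)
  for (int i = 0; i < n_out; ++i) {
    double u = map_index(i, out_orig, out_sp, in_orig, in_sp);
    std::vector<double> w;
    int s0 = 0;
    if (kern == "NN") {
      s0 = (int)std::floor(u + 0.5);
      w.assign(1, 1.0);
    } else if (kern == "L") {
      int f = (int)std::floor(u);
      double t = u - f;
      s0 = f;
      w.resize(2); w[0] = 1.0 - t; w[1] = t;
    } else if (kern == "BS") {
      int f = (int)std::floor(u);
      double t = u - f;
      s0 = f - 1;
      w.resize(4);
      w[0] = (1.0 - t) * (1.0 - t) * (1.0 - t) / 6.0;
      w[1] = (3.0 * t * t * t - 6.0 * t * t + 4.0) / 6.0;
      w[2] = (-3.0 * t * t * t + 3.0 * t * t + 3.0 * t + 1.0) / 6.0;
      w[3] = t * t * t / 6.0;
    } else if (kern == "G" || kern == "LG") {
      double sv = sigma_mm / in_sp; // sigma in input voxels
      if (sv < 1e-8) sv = 1e-8;
      int r = std::max(1, (int)std::ceil(3.0 * sv));
      int f = (int)std::floor(u + 0.5);
      s0 = f - r;
      w.resize(2 * r + 1);
      for (int k = 0; k <= 2 * r; ++k) {
        double d = u - (s0 + k);
        w[k] = std::exp(-0.5 * d * d / (sv * sv));
      }
    } else { // windowed sinc family
      int f = (int)std::floor(u);
      s0 = f - (int)m + 1;
      w.resize(2 * (int)m);
      for (int k = 0; k < 2 * (int)m; ++k) {
        double d = u - (s0 + k);
        w[k] = sinc(d) * window_fun(kern, d, m);
      }
    }
    double tot = 0.0;
    for (size_t k = 0; k < w.size(); ++k) tot += w[k];
    if (tot != 0.0) for (size_t k = 0; k < w.size(); ++k) w[k] /= tot;
    at.start[i] = s0;
    at.w[i] = w;
  }
  return at;
}

static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

// [[Rcpp::export]]
NumericVector resample_grid_cpp(NumericVector values, IntegerVector in_dim,
                                NumericVector in_spacing, NumericVector in_origin,
                                IntegerVector out_dim, NumericVector out_spacing,
                                NumericVector out_origin, std::string kernel,
                                double sigma_mm) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];

  std::vector<double> src(values.begin(), values.end());
  if (kernel == "BS") {
    // prefilter along x, then y, then z
    std::vector<double> line;
    line.resize(std::max(nx, std::max(ny, nz)));
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        std::vector<double> l(nx);
        for (int x = 0; x < nx; ++x) l[x] = src[x + nx * (y + (size_t)ny * z)];
        bspline_prefilter_line(l);
        for (int x = 0; x < nx; ++x) src[x + nx * (y + (size_t)ny * z)] = l[x];
      }
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        std::vector<double> l(ny);
        for (int y = 0; y < ny; ++y) l[y] = src[x + nx * (y + (size_t)ny * z)];
        bspline_prefilter_line(l);
        for (int y = 0; y < ny; ++y) src[x + nx * (y + (size_t)ny * z)] = l[y];
      }
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        std::vector<double> l(nz);
        for (int z = 0; z < nz; ++z) l[z] = src[x + nx * (y + (size_t)ny * z)];
        bspline_prefilter_line(l);
        for (int z = 0; z < nz; ++z) src[x + nx * (y + (size_t)ny * z)] = l[z];
      }
  }

  AxisTaps tx = make_axis_taps(ox, nx, out_origin[0], out_spacing[0], in_origin[0], in_spacing[0], kernel, sigma_mm);
  AxisTaps ty = make_axis_taps(oy, ny, out_origin[1], out_spacing[1], in_origin[1], in_spacing[1], kernel, sigma_mm);
  AxisTaps tz = make_axis_taps(oz, nz, out_origin[2], out_spacing[2], in_origin[2], in_spacing[2], kernel, sigma_mm);

  NumericVector out((R_xlen_t)ox * oy * oz);
  if (kernel == "LG") {
    // label voting with Gaussian weights: output = value with maximal summed weight
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          std::map<double, double> vote;
          const std::vector<double>& wx = tx.w[x];
          const std::vector<double>& wy = ty.w[y];
          const std::vector<double>& wz = tz.w[z];
          for (size_t kz = 0; kz < wz.size(); ++kz) {
            int iz = clampi(tz.start[z] + (int)kz, nz);
            for (size_t ky = 0; ky < wy.size(); ++ky) {
              int iy = clampi(ty.start[y] + (int)ky, ny);
              double wzy = wz[kz] * wy[ky];
              for (size_t kx = 0; kx < wx.size(); ++kx) {
                int ix = clampi(tx.start[x] + (int)kx, nx);
                vote[src[ix + nx * (iy + (size_t)ny * iz)]] += wzy * wx[kx];
              }
            }
          }
          double best = 0.0, bw = -1.0;
          for (std::map<double, double>::iterator it = vote.begin(); it != vote.end(); ++it)
            if (it->second > bw) { bw = it->second; best = it->first; }
          out[x + ox * (y + (size_t)oy * z)] = best;
        }
  } else {
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          double acc = 0.0;
          const std::vector<double>& wx = tx.w[x];
          const std::vector<double>& wy = ty.w[y];
          const std::vector<double>& wz = tz.w[z];
          for (size_t kz = 0; kz < wz.size(); ++kz) {
            int iz = clampi(tz.start[z] + (int)kz, nz);
            for (size_t ky = 0; ky < wy.size(); ++ky) {
              int iy = clampi(ty.start[y] + (int)ky, ny);
              double wzy = wz[kz] * wy[ky];
              double rowacc = 0.0;
              for (size_t kx = 0; kx < wx.size(); ++kx) {
                int ix = clampi(tx.start[x] + (int)kx, nx);
                rowacc += wx[kx] * src[ix + nx * (iy + (size_t)ny * iz)];
              }
              acc += wzy * rowacc;
            }
          }
          out[x + ox * (y + (size_t)oy * z)] = acc;
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// separable Gaussian smoothing, sigma per axis in voxels, reflective boundary
// [[Rcpp::export]]
NumericVector smooth_gaussian_cpp(NumericVector values, IntegerVector dim,
                                  NumericVector sigma_vox) {
  int n[3] = {dim[0], dim[1], dim[2]};
  std::vector<double> a(values.begin(), values.end());
  std::vector<double> b(a.size());
  size_t stride[3] = {1, (size_t)n[0], (size_t)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double tot = 0.0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); tot += k[i + r]; }
    for (int i = 0; i < 2 * r + 1; ++i) k[i] /= tot;
    int n0 = n[ax];
    int n1 = n[(ax + 1) % 3], n2 = n[(ax + 2) % 3];
    size_t s0 = stride[ax], s1 = stride[(ax + 1) % 3], s2 = stride[(ax + 2) % 3];
    for (int j2 = 0; j2 < n2; ++j2)
      for (int j1 = 0; j1 < n1; ++j1) {
        size_t base = j1 * s1 + j2 * s2;
        for (int i = 0; i < n0; ++i) {
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int ii = i + t;
            if (ii < 0) ii = -ii - 1;          // reflect
            if (ii >= n0) ii = 2 * n0 - ii - 1;
            if (ii < 0) ii = 0; if (ii >= n0) ii = n0 - 1;
            acc += k[t + r] * a[base + (size_t)ii * s0];
          }
          b[base + (size_t)i * s0] = acc;
        }
      }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
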