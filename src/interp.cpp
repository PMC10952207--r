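// Resampling, similarity metrics and demons registration kernels.
// Volumes are R arrays in column-major order: v[i + nx*(j + ny*k)], 0-based.
// World mapping: world_mm = A %*% c(i, j, k, 1).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Vol {
  const double* p;
  int nx, ny, nz;
  Vol(const NumericVector& v, const IntegerVector& d)
    : p(v.begin()), nx(d[0]), ny(d[1]), nz(d[2]) {}
  inline double at(int i, int j, int k) const {
    return p[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  }
};

static inline double trilin(const Vol& V, double x, double y, double z,
                            double bg, bool& inb) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > V.nx - 1.0 || y > V.ny - 1.0 || z > V.nz - 1.0) {
    inb = false;
    return bg;
  }
  inb = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > V.nx - 2) x0 = V.nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > V.ny - 2) y0 = V.ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > V.nz - 2) z0 = V.nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (V.nx == 1) { x0 = 0; fx = 0.0; }
  if (V.ny == 1) { y0 = 0; fy = 0.0; }
  if (V.nz == 1) { z0 = 0; fz = 0.0; }
  int x1 = std::min(x0 + 1, V.nx - 1);
  int y1 = std::min(y0 + 1, V.ny - 1);
  int z1 = std::min(z0 + 1, V.nz - 1);
  double c00 = V.at(x0, y0, z0) * (1 - fx) + V.at(x1, y0, z0) * fx;
  double c10 = V.at(x0, y1, z0) * (1 - fx) + V.at(x1, y1, z0) * fx;
  double c01 = V.at(x0, y0, z1) * (1 - fx) + V.at(x1, y0, z1) * fx;
  double c11 = V.at(x0, y1, z1) * (1 - fx) + V.at(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double nearest(const Vol& V, double x, double y, double z,
                             double bg) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || j < 0 || k < 0 || i >= V.nx || j >= V.ny || k >= V.nz) return bg;
  return V.at(i, j, k);
}

// Pull-back resampling onto an output grid.
// P: 4x4 world mm -> moving voxel index; Aout: 4x4 output voxel index -> world mm.
// u (optional): per-voxel world-mm displacement on the output grid, dims
// c(out_dims, 3); the sampled point is P %*% (Aout %*% idx + u(idx)).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector moving, IntegerVector mdims,
                           NumericMatrix P, NumericMatrix Aout,
                           Nullable<NumericVector> u_, IntegerVector odims,
                           bool nearest_mode, double background) {
  Vol V(moving, mdims);
  int nx = odims[0], ny = odims[1], nz = odims[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector out((R_xlen_t)nvox);
  const double* u = nullptr;
  if (u_.isNotNull()) u = NumericVector(u_).begin();
  double a00 = Aout(0,0), a01 = Aout(0,1), a02 = Aout(0,2), a03 = Aout(0,3);
  double a10 = Aout(1,0), a11 = Aout(1,1), a12 = Aout(1,2), a13 = Aout(1,3);
  double a20 = Aout(2,0), a21 = Aout(2,1), a22 = Aout(2,2), a23 = Aout(2,3);
  double p00 = P(0,0), p01 = P(0,1), p02 = P(0,2), p03 = P(0,3);
  double p10 = P(1,0), p11 = P(1,1), p12 = P(1,2), p13 = P(1,3);
  double p20 = P(2,0), p21 = P(2,1), p22 = P(2,2), p23 = P(2,3);
  size_t idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        double wx = a00*i + a01*j + a02*k + a03;
        double wy = a10*i + a11*j + a12*k + a13;
        double wz = a20*i + a21*j + a22*k + a23;
        if (u) {
          wx += u[idx];
          wy += u[idx + nvox];
          wz += u[idx + 2*nvox];
        }
        double mx = p00*wx + p01*wy + p02*wz + p03;
        double my = p10*wx + p11*wy + p12*wz + p13;
        double mz = p20*wx + p21*wy + p22*wz + p23;
        if (nearest_mode) {
          out[idx] = nearest(V, mx, my, mz, background);
        } else {
          bool inb;
          out[idx] = trilin(V, mx, my, mz, background, inb);
        }
      }
  out.attr("dim") = odims;
  return out;
}

// Masked normalized cross-correlation between a fixed image and a moving
// image pulled back through P (world -> moving index). Returns 1 - NCC.
// [[Rcpp::export]]
List cpp_ncc_cost(NumericVector fixed, LogicalVector mask, IntegerVector fdims,
                  NumericVector moving, IntegerVector mdims,
                  NumericMatrix P, NumericMatrix Afix) {
  Vol F(fixed, fdims);
  Vol M(moving, mdims);
  double a00 = Afix(0,0), a01 = Afix(0,1), a02 = Afix(0,2), a03 = Afix(0,3);
  double a10 = Afix(1,0), a11 = Afix(1,1), a12 = Afix(1,2), a13 = Afix(1,3);
  double a20 = Afix(2,0), a21 = Afix(2,1), a22 = Afix(2,2), a23 = Afix(2,3);
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  size_t n = 0, idx = 0;
  for (int k = 0; k < F.nz; k++)
    for (int j = 0; j < F.ny; j++)
      for (int i = 0; i < F.nx; i++, idx++) {
        if (!mask[idx]) continue;
        double wx = a00*i + a01*j + a02*k + a03;
        double wy = a10*i + a11*j + a12*k + a13;
        double wz = a20*i + a21*j + a22*k + a23;
        double mx = P(0,0)*wx + P(0,1)*wy + P(0,2)*wz + P(0,3);
        double my = P(1,0)*wx + P(1,1)*wy + P(1,2)*wz + P(1,3);
        double mz = P(2,0)*wx + P(2,1)*wy + P(2,2)*wz + P(2,3);
        bool inb;
        double mv = trilin(M, mx, my, mz, 0.0, inb);
        if (!inb) continue;
        double fv = F.p[idx];
        sf += fv; sm += mv; sff += fv*fv; smm += mv*mv; sfm += fv*mv;
        n++;
      }
  if (n < 8) return List::create(_["cost"] = 2.0, _["n"] = (double)n);
  double vf = sff - sf*sf/n, vm = smm - sm*sm/n, cv = sfm - sf*sm/n;
  double den = std::sqrt(std::max(vf, 1e-12) * std::max(vm, 1e-12));
  double ncc = cv / den;
  return List::create(_["cost"] = 1.0 - ncc, _["n"] = (double)n);
}

static void gauss1d(std::vector<double>& kern, double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  kern.assign(2*r + 1, 0.0);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    kern[i + r] = v;
    s += v;
  }
  for (auto& v : kern) v /= s;
}

static void smooth_axis(std::vector<double>& buf, double* v,
                        int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  std::vector<double> kern;
  gauss1d(kern, sigma);
  int r = ((int)kern.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  int len = n[axis];
  buf.resize(len);
  int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
  for (int b = 0; b < n[o2]; b++)
    for (int a = 0; a < n[o1]; a++) {
      size_t base = stride[o1]*a + stride[o2]*b;
      for (int t = 0; t < len; t++) buf[t] = v[base + stride[axis]*t];
      for (int t = 0; t < len; t++) {
        double s = 0;
        for (int q = -r; q <= r; q++) {
          int tt = t + q;
          if (tt < 0) tt = -tt;              // reflect
          if (tt > len - 1) tt = 2*(len-1) - tt;
          if (tt < 0) tt = 0;
          s += kern[q + r] * buf[tt];
        }
        v[base + stride[axis]*t] = s;
      }
    }
}

// Separable Gaussian smoothing (sigma per axis, in voxels), reflected edges.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector img, IntegerVector dims,
                               NumericVector sigma_vox) {
  NumericVector out = clone(img);
  std::vector<double> buf;
  smooth_axis(buf, out.begin(), dims[0], dims[1], dims[2], 0, sigma_vox[0]);
  smooth_axis(buf, out.begin(), dims[0], dims[1], dims[2], 1, sigma_vox[1]);
  smooth_axis(buf, out.begin(), dims[0], dims[1], dims[2], 2, sigma_vox[2]);
  out.attr("dim") = img.attr("dim");
  return out;
}

// Demons-style diffeomorphic-ish registration on the fixed grid.
// fixed, moving: intensity volumes; P: world -> moving voxel index (includes
// the inverse of the affine initialization); Afix: fixed index -> world.
// Returns per-voxel world-mm displacement field u with dims c(fdims, 3):
// sampled moving point for fixed voxel y is P %*% (y_world + u).
// [[Rcpp::export]]
NumericVector cpp_demons(NumericVector fixed, IntegerVector fdims,
                         NumericVector moving, IntegerVector mdims,
                         NumericMatrix P, NumericMatrix Afix,
                         NumericVector u0, NumericVector spacing,
                         int iters, double sigma_fluid_vox,
                         double sigma_diff_vox, double cap_mm) {
  int nx = fdims[0], ny = fdims[1], nz = fdims[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector u = clone(u0);
  Vol M(moving, mdims);
  std::vector<double> warped(nvox), du(3 * nvox);
  std::vector<double> buf;
  double spm = (spacing[0] + spacing[1] + spacing[2]) / 3.0;
  double beta = 1.0 / (spm * spm);
  NumericVector svF = NumericVector::create(sigma_fluid_vox, sigma_fluid_vox,
                                            sigma_fluid_vox);
  for (int it = 0; it < iters; it++) {
    // warp moving onto fixed grid through current field
    size_t idx = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, idx++) {
          double wx = Afix(0,0)*i + Afix(0,1)*j + Afix(0,2)*k + Afix(0,3) + u[idx];
          double wy = Afix(1,0)*i + Afix(1,1)*j + Afix(1,2)*k + Afix(1,3) + u[idx + nvox];
          double wz = Afix(2,0)*i + Afix(2,1)*j + Afix(2,2)*k + Afix(2,3) + u[idx + 2*nvox];
          double mx = P(0,0)*wx + P(0,1)*wy + P(0,2)*wz + P(0,3);
          double my = P(1,0)*wx + P(1,1)*wy + P(1,2)*wz + P(1,3);
          double mz = P(2,0)*wx + P(2,1)*wy + P(2,2)*wz + P(2,3);
          bool inb;
          warped[idx] = trilin(M, mx, my, mz, 0.0, inb);
        }
    // demons force from the warped image gradient (central differences, mm)
    idx = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, idx++) {
          int ip = std::min(i+1, nx-1), im = std::max(i-1, 0);
          int jp = std::min(j+1, ny-1), jm = std::max(j-1, 0);
          int kp = std::min(k+1, nz-1), km = std::max(k-1, 0);
          size_t s0 = (size_t)nx * ((size_t)j + (size_t)ny * k);
          size_t sj0 = (size_t)nx * ((size_t)jm + (size_t)ny * k);
          size_t sj1 = (size_t)nx * ((size_t)jp + (size_t)ny * k);
          size_t sk0 = (size_t)nx * ((size_t)j + (size_t)ny * km);
          size_t sk1 = (size_t)nx * ((size_t)j + (size_t)ny * kp);
          double gx = (warped[ip + s0] - warped[im + s0]) / ((ip - im) * spacing[0]);
          double gy = (warped[i + sj1] - warped[i + sj0]) / ((jp - jm) * spacing[1]);
          double gz = (warped[i + sk1] - warped[i + sk0]) / ((kp - km) * spacing[2]);
          double diff = fixed[idx] - warped[idx];
          double g2 = gx*gx + gy*gy + gz*gz;
          double den = g2 + beta * diff * diff;
          double s = (den > 1e-12) ? diff / den : 0.0;
          double dx = s*gx, dy = s*gy, dz = s*gz;
          double nrm = std::sqrt(dx*dx + dy*dy + dz*dz);
          if (nrm > cap_mm) {
            double sc = cap_mm / nrm;
            dx *= sc; dy *= sc; dz *= sc;
          }
          du[idx] = dx; du[idx + nvox] = dy; du[idx + 2*nvox] = dz;
        }
    for (int c = 0; c < 3; c++)
      smooth_axis(buf, du.data() + c*nvox, nx, ny, nz, 0, sigma_fluid_vox),
      smooth_axis(buf, du.data() + c*nvox, nx, ny, nz, 1, sigma_fluid_vox),
      smooth_axis(buf, du.data() + c*nvox, nx, ny, nz, 2, sigma_fluid_vox);
    for (size_t q = 0; q < 3*nvox; q++) u[q] += du[q];
    if (sigma_diff_vox > 0)
      for (int c = 0; c < 3; c++)
        smooth_axis(buf, u.begin() + c*nvox, nx, ny, nz, 0, sigma_diff_vox),
        smooth_axis(buf, u.begin() + c*nvox, nx, ny, nz, 1, sigma_diff_vox),
        smooth_axis(buf, u.begin() + c*nvox, nx, ny, nz, 2, sigma_diff_vox);
  }
  u.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return u;
}

// 6-connected component labelling; returns integer labels (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_cc6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab((R_xlen_t)nvox);
  std::vector<size_t> stack;
  std::vector<double> sizes;
  int cur = 0;
  for (size_t s = 0; s < nvox; s++) {
    if (!mask[s] || lab[s]) continue;
    cur++;
    double cnt = 0;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      cnt++;
      int i = v % nx, j = (v / nx) % ny, k = v / ((size_t)nx * ny);
      const int di[6] = {1,-1,0,0,0,0}, dj[6] = {0,0,1,-1,0,0},
                dk[6] = {0,0,0,0,1,-1};
      for (int q = 0; q < 6; q++) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t w = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
        if (mask[w] && !lab[w]) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(cnt);
  }
  lab.attr("dim") = dims;
  lab.attr("sizes") = wrap(sizes);
  return lab;
}

// Box (Chebyshev) dilation / erosion by radius r, via separable running pass.
// [[Rcpp::export]]
LogicalVector cpp_box_morph(LogicalVector mask, IntegerVector dims, int r,
                            bool dilate) {
  int n[3] = {dims[0], dims[1], dims[2]};
  size_t nvox = (size_t)n[0] * n[1] * n[2];
  std::vector<char> a(nvox), b(nvox);
  for (size_t s = 0; s < nvox; s++) a[s] = mask[s] ? 1 : 0;
  size_t stride[3] = {1, (size_t)n[0], (size_t)n[0] * n[1]};
  for (int axis = 0; axis < 3; axis++) {
    int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3, len = n[axis];
    for (int v2 = 0; v2 < n[o2]; v2++)
      for (int v1 = 0; v1 < n[o1]; v1++) {
        size_t base = stride[o1]*v1 + stride[o2]*v2;
        for (int t = 0; t < len; t++) {
          char acc = dilate ? 0 : 1;
          for (int q = -r; q <= r; q++) {
            int tt = t + q;
            char val = (tt < 0 || tt >= len) ? 0 : a[base + stride[axis]*tt];
            if (dilate) { if (val) { acc = 1; break; } }
            else if (!val) { acc = 0; break; }
          }
          b[base + stride[axis]*t] = acc;
        }
      }
    std::swap(a, b);
  }
  LogicalVector out((R_xlen_t)nvox);
  for (size_t s = 0; s < nvox; s++) out[s] = a[s] != 0;
  out.attr("dim") = dims;
  return out;
}
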