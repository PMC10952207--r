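// Quasi-static surrogate field kernels: Biot-Savart B and vector potential A
// from a discretized current loop, plus ray-marched in-tissue path length
// used for the exponential skin-depth attenuation.
#include <Rcpp.h>
using namespace Rcpp;

static const double MU0_4PI = 1e-7; // mu0 / (4 pi), T*m/A

// B (Tesla) and vector potential A (T*m) at points (meters) from a closed
// polyline loop carrying 1 A, midpoint-rule per segment.
// pts: N x 3 (m); loop: S x 3 ordered vertices (m), implicitly closed.
// [[Rcpp::export]]
List cpp_loop_fields(NumericMatrix pts, NumericMatrix loop, double rmin) {
  int n = pts.nrow(), s = loop.nrow();
  NumericMatrix B(n, 3), A(n, 3);
  std::vector<double> mx(s), my(s), mz(s), dx(s), dy(s), dz(s);
  for (int q = 0; q < s; q++) {
    int q2 = (q + 1) % s;
    mx[q] = 0.5 * (loop(q,0) + loop(q2,0));
    my[q] = 0.5 * (loop(q,1) + loop(q2,1));
    mz[q] = 0.5 * (loop(q,2) + loop(q2,2));
    dx[q] = loop(q2,0) - loop(q,0);
    dy[q] = loop(q2,1) - loop(q,1);
    dz[q] = loop(q2,2) - loop(q,2);
  }
  for (int i = 0; i < n; i++) {
    double px = pts(i,0), py = pts(i,1), pz = pts(i,2);
    double bx = 0, by = 0, bz = 0, ax = 0, ay = 0, az = 0;
    for (int q = 0; q < s; q++) {
      double rx = px - mx[q], ry = py - my[q], rz = pz - mz[q];
      double r2 = rx*rx + ry*ry + rz*rz;
      double r = std::sqrt(r2);
      if (r < rmin) r = rmin;
      double ir3 = 1.0 / (r*r*r);
      // dl x r
      bx += (dy[q]*rz - dz[q]*ry) * ir3;
      by += (dz[q]*rx - dx[q]*rz) * ir3;
      bz += (dx[q]*ry - dy[q]*rx) * ir3;
      double ir = 1.0 / r;
      ax += dx[q] * ir;
      ay += dy[q] * ir;
      az += dz[q] * ir;
    }
    B(i,0) = MU0_4PI * bx; B(i,1) = MU0_4PI * by; B(i,2) = MU0_4PI * bz;
    A(i,0) = MU0_4PI * ax; A(i,1) = MU0_4PI * ay; A(i,2) = MU0_4PI * az;
  }
  return List::create(_["B"] = B, _["A"] = A);
}

// In-tissue path length (mm) along the straight ray from a source point to
// each voxel center. labels: integer volume (0 = air); W2V maps world mm to
// voxel index; V2W the inverse. Sampled at step_mm increments.
// [[Rcpp::export]]
NumericVector cpp_ray_depth(IntegerVector labels, IntegerVector dims,
                            NumericMatrix V2W, NumericMatrix W2V,
                            NumericVector src_mm, double step_mm) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  NumericVector depth((R_xlen_t)nvox);
  double sx = src_mm[0], sy = src_mm[1], sz = src_mm[2];
  size_t idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        double wx = V2W(0,0)*i + V2W(0,1)*j + V2W(0,2)*k + V2W(0,3);
        double wy = V2W(1,0)*i + V2W(1,1)*j + V2W(1,2)*k + V2W(1,3);
        double wz = V2W(2,0)*i + V2W(2,1)*j + V2W(2,2)*k + V2W(2,3);
        double rx = wx - sx, ry = wy - sy, rz = wz - sz;
        double L = std::sqrt(rx*rx + ry*ry + rz*rz);
        int nstep = (int)std::floor(L / step_mm);
        int cnt = 0;
        for (int t = 1; t <= nstep; t++) {
          double f = (t * step_mm) / L;
          double qx = sx + f*rx, qy = sy + f*ry, qz = sz + f*rz;
          double vx = W2V(0,0)*qx + W2V(0,1)*qy + W2V(0,2)*qz + W2V(0,3);
          double vy = W2V(1,0)*qx + W2V(1,1)*qy + W2V(1,2)*qz + W2V(1,3);
          double vz = W2V(2,0)*qx + W2V(2,1)*qy + W2V(2,2)*qz + W2V(2,3);
          int ii = (int)std::lround(vx), jj = (int)std::lround(vy),
              kk = (int)std::lround(vz);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          if (labels[(size_t)ii + (size_t)nx*((size_t)jj + (size_t)ny*kk)] != 0)
            cnt++;
        }
        depth[idx] = cnt * step_mm;
      }
  depth.attr("dim") = dims;
  return depth;
}
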