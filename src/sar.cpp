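// 10 g mass-averaged SAR by voxel-centered cube growing (simplified
// IEC/IEEE 62704-1 rule), per-region Q-matrix construction via 3D prefix
// sums, exact per-shim maximum evaluation with eigenvalue pruning, and
// greedy VOP compression.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using cplx = std::complex<double>;

// 3D inclusive prefix sum; out has dims (nx+1, ny+1, nz+1).
template <typename T>
static void prefix3(const T* v, int nx, int ny, int nz, std::vector<T>& P) {
  size_t px = nx + 1, py = ny + 1, pz = nz + 1;
  P.assign(px * py * pz, T(0));
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t o = (size_t)(i+1) + px * ((size_t)(j+1) + py * (size_t)(k+1));
        P[o] = v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)]
             + P[o - 1]
             + P[o - px]
             + P[o - px*py]
             - P[o - 1 - px]
             - P[o - 1 - px*py]
             - P[o - px - px*py]
             + P[o - 1 - px - px*py];
      }
}

template <typename T>
static inline T cubesum(const std::vector<T>& P, size_t px, size_t py,
                        int i0, int i1, int j0, int j1, int k0, int k1) {
  // inclusive voxel bounds, assumed already clamped to the grid
  size_t a0 = i0, a1 = i1 + 1, b0 = j0, b1 = j1 + 1, c0 = k0, c1 = k1 + 1;
  return P[a1 + px*(b1 + py*c1)] - P[a0 + px*(b1 + py*c1)]
       - P[a1 + px*(b0 + py*c1)] - P[a1 + px*(b1 + py*c0)]
       + P[a0 + px*(b0 + py*c1)] + P[a0 + px*(b1 + py*c0)]
       + P[a1 + px*(b0 + py*c0)] - P[a0 + px*(b0 + py*c0)];
}

static inline void clampb(int c, int h, int n, int& lo, int& hi) {
  lo = c - h; if (lo < 0) lo = 0;
  hi = c + h; if (hi > n - 1) hi = n - 1;
}

// Cube-growing 10 g averaging. mass, power: per-voxel kg and W; head: region
// eligibility mask. For each eligible voxel with mass > 0 the cube grows in
// odd side lengths until the enclosed mass reaches target_kg; the outermost
// layer is weighted fractionally so the enclosed mass equals target_kg
// exactly. Voxels whose cube would exceed smax take the maximum over valid
// cubes containing them (painted, valid = FALSE).
// [[Rcpp::export]]
List cpp_sar10g(NumericVector mass, NumericVector power, IntegerVector dims,
                LogicalVector head, double target_kg, int smax) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz, px = nx + 1, py = ny + 1;
  std::vector<double> PM, PP;
  prefix3(mass.begin(), nx, ny, nz, PM);
  prefix3(power.begin(), nx, ny, nz, PP);
  NumericVector sar((R_xlen_t)nvox), frac((R_xlen_t)nvox);
  IntegerVector side((R_xlen_t)nvox);
  LogicalVector valid((R_xlen_t)nvox);
  std::vector<char> center(nvox, 0), inval(nvox, 0);
  size_t idx = 0;
  int hmax = (smax - 1) / 2;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        if (!head[idx] || mass[idx] <= 0) continue;
        center[idx] = 1;
        double m_in = 0, p_in = 0;
        bool done = false;
        for (int h = 0; h <= hmax; h++) {
          int i0, i1, j0, j1, k0, k1;
          clampb(i, h, nx, i0, i1);
          clampb(j, h, ny, j0, j1);
          clampb(k, h, nz, k0, k1);
          double m = cubesum(PM, px, py, i0, i1, j0, j1, k0, k1);
          if (m >= target_kg) {
            double p = cubesum(PP, px, py, i0, i1, j0, j1, k0, k1);
            double f = (m > m_in) ? (target_kg - m_in) / (m - m_in) : 1.0;
            sar[idx] = (p_in + f * (p - p_in)) / target_kg;
            side[idx] = 2*h + 1;
            frac[idx] = f;
            valid[idx] = true;
            done = true;
            break;
          }
          m_in = m;
          p_in = cubesum(PP, px, py, i0, i1, j0, j1, k0, k1);
        }
        if (!done) inval[idx] = 1;
      }
  // paint invalid voxels with the max over valid cubes containing them
  std::vector<double> PI;
  {
    std::vector<double> iv(nvox);
    for (size_t s = 0; s < nvox; s++) iv[s] = inval[s] ? 1.0 : 0.0;
    prefix3(iv.data(), nx, ny, nz, PI);
  }
  idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        if (!valid[idx]) continue;
        int h = (side[idx] - 1) / 2;
        int i0, i1, j0, j1, k0, k1;
        clampb(i, h, nx, i0, i1);
        clampb(j, h, ny, j0, j1);
        clampb(k, h, nz, k0, k1);
        if (cubesum(PI, px, py, i0, i1, j0, j1, k0, k1) < 0.5) continue;
        for (int kk = k0; kk <= k1; kk++)
          for (int jj = j0; jj <= j1; jj++)
            for (int ii = i0; ii <= i1; ii++) {
              size_t w = (size_t)ii + (size_t)nx*((size_t)jj + (size_t)ny*kk);
              if (inval[w] && sar[idx] > sar[w]) sar[w] = sar[idx];
            }
      }
  sar.attr("dim") = dims;
  side.attr("dim") = dims;
  frac.attr("dim") = dims;
  valid.attr("dim") = dims;
  return List::create(_["sar10g"] = sar, _["side"] = side, _["frac"] = frac,
                      _["valid"] = valid);
}

// Packed upper-triangle Q matrices for all regions.
// E: complex array dims c(nx,ny,nz,3,nch) (V/m, unit drive, 1 W/channel);
// sigma: S/m per voxel. centers: 0-based linear indices of region centers;
// side/frac: cube geometry from cpp_sar10g. Pack order q = (c <= c'),
// column-major over the upper triangle; entry Q[c,c'] (see build_q_matrices).
// Q[c,c'] = sum_v f_v sigma_v (E_{c'}(v) . conj(E_c(v))) dV / (2 target_kg),
// which guarantees w^H Q w = 10g SAR of the combined field sum_c w_c E_c.
// [[Rcpp::export]]
ComplexMatrix cpp_qpack(ComplexVector E, IntegerVector dims, int nch,
                        NumericVector sigma, IntegerVector centers,
                        IntegerVector side, NumericVector frac,
                        double voxvol_m3, double target_kg) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz, px = nx + 1, py = ny + 1;
  int nreg = centers.size();
  int npair = nch * (nch + 1) / 2;
  ComplexMatrix pack(npair, nreg);
  const cplx* Ep = reinterpret_cast<const cplx*>(COMPLEX(E));
  std::vector<cplx> svol(nvox);
  std::vector<cplx> P;
  double scale = voxvol_m3 / (2.0 * target_kg);
  int q = 0;
  for (int c2 = 0; c2 < nch; c2++)
    for (int c1 = 0; c1 <= c2; c1++, q++) {
      const cplx* Ea = Ep + (size_t)3 * nvox * c1; // conj side
      const cplx* Eb = Ep + (size_t)3 * nvox * c2;
      for (size_t v = 0; v < nvox; v++) {
        if (sigma[v] <= 0) { svol[v] = 0.0; continue; }
        cplx s = Eb[v] * std::conj(Ea[v])
               + Eb[v + nvox] * std::conj(Ea[v + nvox])
               + Eb[v + 2*nvox] * std::conj(Ea[v + 2*nvox]);
        svol[v] = sigma[v] * s;
      }
      prefix3(svol.data(), nx, ny, nz, P);
      for (int r = 0; r < nreg; r++) {
        size_t cidx = centers[r];
        int i = cidx % nx, jj = (cidx / nx) % ny, kk = cidx / ((size_t)nx*ny);
        int h = (side[r] - 1) / 2;
        int i0, i1, j0, j1, k0, k1;
        clampb(i, h, nx, i0, i1);
        clampb(jj, h, ny, j0, j1);
        clampb(kk, h, nz, k0, k1);
        cplx outer = cubesum(P, px, py, i0, i1, j0, j1, k0, k1);
        cplx inner = 0.0;
        if (h > 0) {
          int hi = h - 1;
          int a0, a1, b0, b1, c0, c1;
          clampb(i, hi, nx, a0, a1);
          clampb(jj, hi, ny, b0, b1);
          clampb(kk, hi, nz, c0, c1);
          inner = cubesum(P, px, py, a0, a1, b0, b1, c0, c1);
        }
        cplx val = (inner + frac[r] * (outer - inner)) * scale;
        pack(q, r) = Rcomplex{val.real(), val.imag()};
      }
    }
  return pack;
}

static void unpack_herm(const cplx* col, int nch, arma::cx_mat& Q) {
  int q = 0;
  for (int c2 = 0; c2 < nch; c2++)
    for (int c1 = 0; c1 <= c2; c1++, q++) {
      Q(c1, c2) = col[q];
      Q(c2, c1) = std::conj(col[q]);
    }
  // enforce real diagonal
  for (int c = 0; c < nch; c++) Q(c, c) = cplx(Q(c, c).real(), 0.0);
}

// Largest eigenvalue per packed region matrix.
// [[Rcpp::export]]
NumericVector cpp_pack_eigmax(ComplexMatrix pack, int nch) {
  int nreg = pack.ncol();
  NumericVector out(nreg);
  arma::cx_mat Q(nch, nch);
  const cplx* base = reinterpret_cast<const cplx*>(COMPLEX(pack));
  int npair = pack.nrow();
  arma::vec ev;
  for (int r = 0; r < nreg; r++) {
    unpack_herm(base + (size_t)npair * r, nch, Q);
    arma::eig_sym(ev, Q);
    out[r] = ev(nch - 1);
  }
  return out;
}

// Exact per-shim max over regions of Re(w^H Q w). pack columns must be
// sorted by descending eigmax when prune = TRUE (eigmax in the same order).
// shims: complex matrix nch x nshim. Returns max value and 0-based argmax.
// [[Rcpp::export]]
List cpp_eval_exact(ComplexMatrix pack, int nch, NumericVector eigmax,
                    ComplexMatrix shims, bool prune) {
  int nreg = pack.ncol(), nshim = shims.ncol();
  int npair = pack.nrow();
  const cplx* base = reinterpret_cast<const cplx*>(COMPLEX(pack));
  const cplx* W = reinterpret_cast<const cplx*>(COMPLEX(shims));
  NumericVector vals(nshim);
  IntegerVector arg(nshim);
  std::vector<double> cr(npair), ci(npair);
  for (int s = 0; s < nshim; s++) {
    const cplx* w = W + (size_t)nch * s;
    double w2 = 0;
    int q = 0;
    for (int c2 = 0; c2 < nch; c2++)
      for (int c1 = 0; c1 <= c2; c1++, q++) {
        if (c1 == c2) {
          cr[q] = std::norm(w[c1]);
          ci[q] = 0.0;
          w2 += cr[q];
        } else {
          cplx t = 2.0 * std::conj(w[c1]) * w[c2];
          cr[q] = t.real();
          ci[q] = t.imag();
        }
      }
    double best = -1e300;
    int bestr = -1;
    for (int r = 0; r < nreg; r++) {
      if (prune && eigmax[r] * w2 <= best) break;
      const cplx* col = base + (size_t)npair * r;
      double v = 0;
      // Re(sum_q pack_q * coeff_q) with coeff = conj pairing above
      for (int t = 0; t < npair; t++)
        v += col[t].real() * cr[t] - col[t].imag() * ci[t];
      if (v > best) { best = v; bestr = r; }
    }
    vals[s] = best;
    arg[s] = bestr;
  }
  return List::create(_["max"] = vals, _["which"] = arg);
}

// PSD within tolerance: attempt Cholesky of M + tol*I (fast fail).
static bool psd_ok(const arma::cx_mat& M, double tol_abs) {
  arma::cx_mat A = M;
  A.diag() += tol_abs;
  arma::cx_mat L;
  return arma::chol(L, A, "lower");
}

// Greedy VOP compression over packed Q matrices sorted by descending
// spectral norm. mode 1 ("proportional"): Q joins VOP core V when
// (1+lambda) V - Q is PSD; mode 2 ("scaled_identity"): when
// V + lambda*normmax*I - Q is PSD. Candidate VOPs are scanned in
// move-to-front order with a cheap diagonal prefilter before the Cholesky
// PSD test. Returns core indices (0-based, into the supplied ordering) and
// per-region VOP assignment.
// [[Rcpp::export]]
List cpp_vop_compress(ComplexMatrix pack, int nch, NumericVector eigmax,
                      double lambda, int mode) {
  int nreg = pack.ncol(), npair = pack.nrow();
  const cplx* base = reinterpret_cast<const cplx*>(COMPLEX(pack));
  double normmax = nreg ? eigmax[0] : 0.0;
  double tol_abs = 1e-9 * std::max(1e-300, normmax);
  double zdiag = (mode == 2) ? lambda * normmax : 0.0;
  std::vector<arma::cx_mat> vops;
  std::vector<arma::vec> vdiag;   // diagonal of V + Z, for the prefilter
  std::vector<int> cores;
  std::vector<int> order;          // move-to-front scan order
  IntegerVector assign(nreg);
  arma::cx_mat Q(nch, nch), M(nch, nch);
  for (int r = 0; r < nreg; r++) {
    unpack_herm(base + (size_t)npair * r, nch, Q);
    arma::vec qd = arma::real(Q.diag());
    int hit = -1;
    for (size_t oi = 0; oi < order.size(); oi++) {
      int v = order[oi];
      // necessary condition: diag(V + Z - Q) >= -tol
      const arma::vec& dv = vdiag[v];
      bool ok = true;
      for (int c = 0; c < nch; c++)
        if (dv(c) - qd(c) < -tol_abs) { ok = false; break; }
      if (!ok) continue;
      if (mode == 1)
        M = (1.0 + lambda) * vops[v] - Q;
      else {
        M = vops[v] - Q;
        M.diag() += zdiag;
      }
      if (psd_ok(M, tol_abs)) {
        hit = v;
        if (oi > 0) {  // move to front
          order.erase(order.begin() + oi);
          order.insert(order.begin(), v);
        }
        break;
      }
    }
    if (hit < 0) {
      vops.push_back(Q);
      arma::vec dv = arma::real(Q.diag());
      if (mode == 1) dv *= (1.0 + lambda);
      else dv += zdiag;
      vdiag.push_back(dv);
      cores.push_back(r);
      hit = (int)vops.size() - 1;
      order.insert(order.begin(), hit);
    }
    assign[r] = hit + 1;
  }
  IntegerVector ci(cores.size());
  for (size_t v = 0; v < cores.size(); v++) ci[v] = cores[v];
  return List::create(_["cores"] = ci, _["assign"] = assign,
                      _["n_vop"] = (int)cores.size());
}

// Per-shim VOP bound: max over cores of Re(w^H (V + Z) w).
// [[Rcpp::export]]
NumericVector cpp_vop_eval(ComplexMatrix pack, int nch, IntegerVector cores,
                           double lambda, int mode, double normmax,
                           ComplexMatrix shims) {
  int nshim = shims.ncol(), nvop = cores.size(), npair = pack.nrow();
  const cplx* base = reinterpret_cast<const cplx*>(COMPLEX(pack));
  const cplx* W = reinterpret_cast<const cplx*>(COMPLEX(shims));
  NumericVector vals(nshim);
  std::vector<double> cr(npair), ci(npair);
  for (int s = 0; s < nshim; s++) {
    const cplx* w = W + (size_t)nch * s;
    double w2 = 0;
    int q = 0;
    for (int c2 = 0; c2 < nch; c2++)
      for (int c1 = 0; c1 <= c2; c1++, q++) {
        if (c1 == c2) {
          cr[q] = std::norm(w[c1]);
          ci[q] = 0.0;
          w2 += cr[q];
        } else {
          cplx t = 2.0 * std::conj(w[c1]) * w[c2];
          cr[q] = t.real();
          ci[q] = t.imag();
        }
      }
    double best = -1e300;
    for (int v = 0; v < nvop; v++) {
      const cplx* col = base + (size_t)npair * cores[v];
      double val = 0;
      for (int t = 0; t < npair; t++)
        val += col[t].real() * cr[t] - col[t].imag() * ci[t];
      if (mode == 1) val *= (1.0 + lambda);
      else val += lambda * normmax * w2;
      if (val > best) best = val;
    }
    vals[s] = best;
  }
  return vals;
}
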