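// Staggered-grid (MAC) kernels for the incompressible Navier-Stokes solver:
// convection/diffusion tendencies, divergence, pressure projection, a
// geometric multigrid Poisson solver on non-uniform Cartesian grids, sharp
// ray-parity solid classification, membrane-distance classification for the
// zero-thickness wings, and trilinear interpolation of staggered fields.
//
// Array layout (column-major, as passed from R):
//   u: (nxu, ny, nz) with nxu = nx for x-periodic grids else nx+1 (x-faces)
//   v: (nx, nyv, nz), w: (nx, ny, nzw) analogously
//   p and cell scalars: (nx, ny, nz) at cell centres
// Boundary codes per face (xlo,xhi,ylo,yhi,zlo,zhi):
//   0 = inflow (Dirichlet U in x, 0 tangential), 1 = outflow (zero gradient),
//   2 = free slip, 3 = periodic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const int BC_INFLOW = 0, BC_OUTFLOW = 1, BC_SLIP = 2, BC_PERIODIC = 3;

struct Axis {
  int n;                      // number of cells
  bool periodic;
  std::vector<double> f;      // faces, length n+1
  std::vector<double> c;      // centres, length n
  double dx(int i) const {    // cell width, wrapped
    int ii = ((i % n) + n) % n;
    return f[ii + 1] - f[ii];
  }
  // distance between centres i-1 and i (face-i normal spacing), i in 0..n
  double cdist(int i) const {
    if (i >= 1 && i <= n - 1) return c[i] - c[i - 1];
    if (periodic) return (f[n] - c[n - 1]) + (c[0] - f[0]);
    if (i <= 0) return 2.0 * (c[0] - f[0]);
    return 2.0 * (f[n] - c[n - 1]);
  }
};

struct Grid {
  Axis ax[3];
  int bc[6];
  double Uin;
};

static Grid make_grid(const List& g) {
  Grid G;
  NumericVector xf = g["xf"], yf = g["yf"], zf = g["zf"];
  IntegerVector bc = g["bc_code"];
  G.Uin = as<double>(g["Uin"]);
  NumericVector fs[3] = {xf, yf, zf};
  for (int d = 0; d < 3; ++d) {
    Axis& a = G.ax[d];
    a.n = fs[d].size() - 1;
    a.f.assign(fs[d].begin(), fs[d].end());
    a.c.resize(a.n);
    for (int i = 0; i < a.n; ++i) a.c[i] = 0.5 * (a.f[i] + a.f[i + 1]);
    a.periodic = (bc[2 * d] == BC_PERIODIC);
  }
  for (int i = 0; i < 6; ++i) G.bc[i] = bc[i];
  return G;
}

// dimensions of the staggered array for component comp
static void comp_dims(const Grid& G, int comp, int dims[3]) {
  for (int d = 0; d < 3; ++d) {
    dims[d] = G.ax[d].n;
    if (d == comp && !G.ax[d].periodic) dims[d] += 1;
  }
}

struct Field {
  const double* a;
  int d0, d1, d2;
  double at(int i, int j, int k) const { return a[i + (size_t)d0 * (j + (size_t)d1 * k)]; }
};

// value of staggered component comp at (possibly ghost) index, applying BCs.
// idx along comp's own axis must be a valid face index (wrapped if periodic);
// along other axes indices may be -1 or n (one ghost layer).
static double stag_val(const Grid& G, int comp, const Field& F, int i0, int i1, int i2) {
  // fast path: all indices in bounds (the overwhelmingly common case)
  if (i0 >= 0 && i0 < F.d0 && i1 >= 0 && i1 < F.d1 && i2 >= 0 && i2 < F.d2)
    return F.at(i0, i1, i2);
  int idx[3] = {i0, i1, i2};
  double sign = 1.0;
  const int dims[3] = {F.d0, F.d1, F.d2};
  for (int d = 0; d < 3; ++d) {
    int n = dims[d];
    if (G.ax[d].periodic) {
      while (idx[d] < 0) idx[d] += n;
      while (idx[d] >= n) idx[d] -= n;
      continue;
    }
    if (idx[d] >= 0 && idx[d] < n) continue;
    // ghost along a non-periodic axis (only happens for d != comp)
    int face = (idx[d] < 0) ? G.bc[2 * d] : G.bc[2 * d + 1];
    int clamped = (idx[d] < 0) ? 0 : n - 1;
    if (face == BC_INFLOW) {           // tangential velocity 0 at inflow
      sign *= -1.0;
      idx[d] = clamped;
    } else {                           // outflow / slip: zero gradient
      idx[d] = clamped;
    }
  }
  return sign * F.at(idx[0], idx[1], idx[2]);
}

// ----------------------------------------------------------------------
// convection + diffusion tendencies
// ----------------------------------------------------------------------

// nonuniform central first derivative from values (fm, f0, fp) at spacings hm, hp
static inline double d1(double fm, double f0, double fp, double hm, double hp) {
  return (hm * hm * fp - hp * hp * fm + (hp * hp - hm * hm) * f0) /
         (hm * hp * (hm + hp));
}
static inline double d2(double fm, double f0, double fp, double hm, double hp) {
  return 2.0 * (hm * fp + hp * fm - (hm + hp) * f0) / (hm * hp * (hm + hp));
}

// tight interior kernel for component c on non-periodic grids: all stencil
// and averaging indices in bounds, constant strides, precomputed spacings
static void conv_diff_interior(const Grid& G, int c, const Field F[3],
                               double nu, double* R) {
  int dims[3]; comp_dims(G, c, dims);
  const size_t str[3] = {1, (size_t)dims[0], (size_t)dims[0] * dims[1]};
  int od[2]; { int t = 0; for (int d = 0; d < 3; ++d) if (d != c) od[t++] = d; }
  // spacings per axis index
  std::vector<double> hm[3], hp[3];
  for (int d = 0; d < 3; ++d) {
    int n = dims[d];
    hm[d].resize(n); hp[d].resize(n);
    for (int i = 0; i < n; ++i) {
      if (d == c) { hm[d][i] = G.ax[d].dx(i - 1); hp[d][i] = G.ax[d].dx(i); }
      else { hm[d][i] = G.ax[d].cdist(i); hp[d][i] = G.ax[d].cdist(i + 1); }
    }
  }
  // averaging strides for the two transverse components
  int dimsO[2][3]; Field FO[2];
  size_t strO[2][3];
  for (int t = 0; t < 2; ++t) {
    comp_dims(G, od[t], dimsO[t]);
    FO[t] = F[od[t]];
    strO[t][0] = 1; strO[t][1] = dimsO[t][0];
    strO[t][2] = (size_t)dimsO[t][0] * dimsO[t][1];
  }
  int lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    if (d == c) { lo[d] = 1; hi[d] = dims[d] - 1; }
    else { lo[d] = 1; hi[d] = dims[d] - 1; }   // transverse shell handled by caller
  }
  // widths for the divergence-form fluxes
  std::vector<double> wdiv[3];
  for (int d = 0; d < 3; ++d) {
    int n = dims[d];
    wdiv[d].resize(n);
    for (int i = 0; i < n; ++i)
      wdiv[d][i] = (d == c) ? G.ax[d].cdist(i) : G.ax[d].dx(i);
  }
  for (int k = lo[2]; k < hi[2]; ++k)
    for (int j = lo[1]; j < hi[1]; ++j) {
      size_t row = str[1] * j + str[2] * k;
      for (int i = lo[0]; i < hi[0]; ++i) {
        size_t id = i + row;
        const int ii[3] = {i, j, k};
        double q0 = F[c].a[id];
        double conv_adv = 0.0, conv_div = 0.0, diff = 0.0;
        for (int d = 0; d < 3; ++d) {
          double fm = F[c].a[id - str[d]];
          double fp = F[c].a[id + str[d]];
          double Hm = hm[d][ii[d]], Hp = hp[d][ii[d]];
          if (d == c) {
            conv_adv += q0 * d1(fm, q0, fp, Hm, Hp);
            double up = 0.5 * (q0 + fp), um = 0.5 * (q0 + fm);
            conv_div += (up * up - um * um) / wdiv[d][ii[d]];
          } else {
            int t = (d == od[0]) ? 0 : 1;
            // comp d at the comp-c point: centres (ii[c]-1, ii[c]) along
            // axis c, faces (ii[d], ii[d]+1) along axis d
            int jj[3] = {ii[0], ii[1], ii[2]};
            jj[c] -= 1;   // centre index below the face
            size_t base = jj[0] * strO[t][0] + jj[1] * strO[t][1] + jj[2] * strO[t][2];
            double vdm = 0.5 * (FO[t].a[base] + FO[t].a[base + strO[t][c]]);
            double vdp = 0.5 * (FO[t].a[base + strO[t][d]] +
                                FO[t].a[base + strO[t][c] + strO[t][d]]);
            conv_adv += 0.5 * (vdm + vdp) * d1(fm, q0, fp, Hm, Hp);
            conv_div += (vdp * 0.5 * (q0 + fp) - vdm * 0.5 * (q0 + fm)) /
                        wdiv[d][ii[d]];
          }
          diff += d2(fm, q0, fp, Hm, Hp);
        }
        // skew-symmetric convection: mean of advective and divergence forms
        R[id] = -0.5 * (conv_adv + conv_div) + nu * diff;
      }
    }
}

// [[Rcpp::export]]
List cpp_conv_diff(NumericVector u, NumericVector v, NumericVector w,
                   List grid, double nu, bool force_general = false) {
  Grid G = make_grid(grid);
  const NumericVector* arrs[3] = {&u, &v, &w};
  Field F[3];
  for (int c = 0; c < 3; ++c) {
    int dims[3]; comp_dims(G, c, dims);
    F[c].a = arrs[c]->begin(); F[c].d0 = dims[0]; F[c].d1 = dims[1]; F[c].d2 = dims[2];
  }
  bool any_periodic = G.ax[0].periodic || G.ax[1].periodic || G.ax[2].periodic;
  List out(3);
  for (int c = 0; c < 3; ++c) {
    int dims[3]; comp_dims(G, c, dims);
    NumericVector rhs((size_t)dims[0] * dims[1] * dims[2]);
    rhs.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2]);
    double* R = rhs.begin();
    const Axis& ac = G.ax[c];
    int lo[3] = {0, 0, 0}, hi[3] = {dims[0], dims[1], dims[2]};
    if (!ac.periodic) { lo[c] = 1; hi[c] = dims[c] - 1; }  // boundary faces fixed by BCs

    bool fast = !any_periodic && !force_general;
    if (fast) conv_diff_interior(G, c, F, nu, R);

    int i[3];
    for (i[2] = lo[2]; i[2] < hi[2]; ++i[2])
      for (i[1] = lo[1]; i[1] < hi[1]; ++i[1])
        for (i[0] = lo[0]; i[0] < hi[0]; ++i[0]) {
          if (fast &&
              i[0] > 0 && i[0] < dims[0] - 1 &&
              i[1] > 0 && i[1] < dims[1] - 1 &&
              i[2] > 0 && i[2] < dims[2] - 1) continue;  // interior done
          double q0 = F[c].at(i[0], i[1], i[2]);
          double conv_adv = 0.0, conv_div = 0.0, diff = 0.0;
          for (int d = 0; d < 3; ++d) {
            int im[3] = {i[0], i[1], i[2]}, ip[3] = {i[0], i[1], i[2]};
            im[d] -= 1; ip[d] += 1;
            double fm = stag_val(G, c, F[c], im[0], im[1], im[2]);
            double fp = stag_val(G, c, F[c], ip[0], ip[1], ip[2]);
            double hm, hp, wdiv;
            if (d == c) {              // along own axis: face-to-face spacing
              hm = ac.dx(i[d] - 1); hp = ac.dx(i[d]);
              wdiv = ac.cdist(i[d]);
            } else {                   // centre-to-centre spacing
              hm = G.ax[d].cdist(i[d]); hp = G.ax[d].cdist(i[d] + 1);
              wdiv = G.ax[d].dx(i[d]);
            }
            if (d == c) {
              conv_adv += q0 * d1(fm, q0, fp, hm, hp);
              double up = 0.5 * (q0 + fp), um = 0.5 * (q0 + fm);
              conv_div += (up * up - um * um) / wdiv;
            } else {
              // component d interpolated to the two d-faces of this cell
              int cc = i[c];           // face index along axis c -> centres cc-1, cc
              double vfaces[2];
              for (int a2 = 0; a2 < 2; ++a2) {
                double s = 0.0;
                for (int a1 = 0; a1 < 2; ++a1) {
                  int jj[3] = {i[0], i[1], i[2]};
                  jj[c] = cc - 1 + a1;        // centre index along axis c
                  jj[d] = i[d] + a2;          // face index along axis d
                  // clamp centre index along c at physical boundaries
                  if (!G.ax[c].periodic) {
                    if (jj[c] < 0) jj[c] = 0;
                    if (jj[c] > G.ax[c].n - 1) jj[c] = G.ax[c].n - 1;
                  }
                  s += stag_val(G, d, F[d], jj[0], jj[1], jj[2]);
                }
                vfaces[a2] = 0.5 * s;
              }
              conv_adv += 0.5 * (vfaces[0] + vfaces[1]) * d1(fm, q0, fp, hm, hp);
              conv_div += (vfaces[1] * 0.5 * (q0 + fp) -
                           vfaces[0] * 0.5 * (q0 + fm)) / wdiv;
            }
            diff += d2(fm, q0, fp, hm, hp);
          }
          // skew-symmetric convection: mean of advective and divergence forms
          R[i[0] + (size_t)dims[0] * (i[1] + (size_t)dims[1] * i[2])] =
            -0.5 * (conv_adv + conv_div) + nu * diff;
        }
    out[c] = rhs;
  }
  out.names() = CharacterVector::create("du", "dv", "dw");
  return out;
}

// ----------------------------------------------------------------------
// divergence, boundary conditions, projection
// ----------------------------------------------------------------------

// face value of component c on face i (0..n) of its own axis
static inline double face_val(const Grid& G, int c, const Field& F, int fi, int j, int k) {
  int idx[3]; idx[c] = fi;
  int oth[2]; int t = 0;
  for (int d = 0; d < 3; ++d) if (d != c) oth[t++] = d;
  idx[oth[0]] = j; idx[oth[1]] = k;
  return stag_val(G, c, F, idx[0], idx[1], idx[2]);
}

// [[Rcpp::export]]
NumericVector cpp_divergence(NumericVector u, NumericVector v, NumericVector w,
                             List grid) {
  Grid G = make_grid(grid);
  const NumericVector* arrs[3] = {&u, &v, &w};
  Field F[3];
  for (int c = 0; c < 3; ++c) {
    int dims[3]; comp_dims(G, c, dims);
    F[c].a = arrs[c]->begin(); F[c].d0 = dims[0]; F[c].d1 = dims[1]; F[c].d2 = dims[2];
  }
  int nx = G.ax[0].n, ny = G.ax[1].n, nz = G.ax[2].n;
  NumericVector div((size_t)nx * ny * nz);
  div.attr("dim") = IntegerVector::create(nx, ny, nz);
  double* D = div.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id[3] = {i, j, k};
        double s = 0.0;
        for (int c = 0; c < 3; ++c) {
          int oth[2]; int t = 0;
          for (int d = 0; d < 3; ++d) if (d != c) oth[t++] = d;
          double qm = face_val(G, c, F[c], id[c], id[oth[0]], id[oth[1]]);
          double qp = face_val(G, c, F[c], id[c] + 1, id[oth[0]], id[oth[1]]);
          s += (qp - qm) / G.ax[c].dx(id[c]);
        }
        D[i + (size_t)nx * (j + (size_t)ny * k)] = s;
      }
  return div;
}

// [[Rcpp::export]]
List cpp_apply_bc(NumericVector u, NumericVector v, NumericVector w, List grid,
                  double dt = 0.0) {
  Grid G = make_grid(grid);
  int du[3], dv[3], dw[3];
  comp_dims(G, 0, du); comp_dims(G, 1, dv); comp_dims(G, 2, dw);
  double* U = u.begin(); double* V = v.begin(); double* W = w.begin();
  size_t sxu = du[0], sxv = dv[0], sxw = dw[0];
  int nx = G.ax[0].n, ny = G.ax[1].n, nz = G.ax[2].n;

  // normal components on non-periodic boundary faces; outflow uses a
  // convective condition du/dt + Uc du/dx = 0 (upwind, explicit), which
  // lets wake vortices leave without reflection; dt = 0 degenerates to a
  // zero-gradient condition
  if (!G.ax[0].periodic) {
    double cco = 0.0;
    if (dt > 0.0 && G.Uin > 0.0)
      cco = std::min(1.0, G.Uin * dt / G.ax[0].cdist(G.ax[0].n));
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        size_t lo = 0 + sxu * (j + (size_t)du[1] * k);
        size_t hi = (du[0] - 1) + sxu * (j + (size_t)du[1] * k);
        if (G.bc[0] == BC_INFLOW) U[lo] = G.Uin;
        else if (G.bc[0] == BC_SLIP) U[lo] = 0.0;
        else if (G.bc[0] == BC_OUTFLOW) U[lo] = U[lo + 1];
        if (G.bc[1] == BC_OUTFLOW) {
          if (cco > 0.0) U[hi] -= cco * (U[hi] - U[hi - 1]);
          else U[hi] = U[hi - 1];
        }
        else if (G.bc[1] == BC_SLIP) U[hi] = 0.0;
        else if (G.bc[1] == BC_INFLOW) U[hi] = G.Uin;
      }
    // global mass balance: distribute flux defect over the outflow face
    if (G.bc[1] == BC_OUTFLOW || G.bc[0] == BC_OUTFLOW) {
      double qin = 0.0, qout = 0.0, aout = 0.0;
      int outHi = (G.bc[1] == BC_OUTFLOW);
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          double da = G.ax[1].dx(j) * G.ax[2].dx(k);
          size_t lo = 0 + sxu * (j + (size_t)du[1] * k);
          size_t hi = (du[0] - 1) + sxu * (j + (size_t)du[1] * k);
          qin += U[outHi ? lo : hi] * da;
          qout += U[outHi ? hi : lo] * da;
          aout += da;
        }
      double corr = (qin - qout) / aout;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
          size_t hi = (outHi ? (size_t)(du[0] - 1) : 0) + sxu * (j + (size_t)du[1] * k);
          U[hi] += corr;
        }
    }
  }
  if (!G.ax[1].periodic) {
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        size_t lo = i + sxv * (0 + (size_t)dv[1] * k);
        size_t hi = i + sxv * ((dv[1] - 1) + (size_t)dv[1] * k);
        if (G.bc[2] == BC_SLIP || G.bc[2] == BC_INFLOW) V[lo] = 0.0;
        else if (G.bc[2] == BC_OUTFLOW) V[lo] = V[lo + sxv];
        if (G.bc[3] == BC_SLIP || G.bc[3] == BC_INFLOW) V[hi] = 0.0;
        else if (G.bc[3] == BC_OUTFLOW) V[hi] = V[hi - sxv];
      }
  }
  if (!G.ax[2].periodic) {
    size_t pl = (size_t)dw[0] * dw[1];
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t lo = i + sxw * j;
        size_t hi = i + sxw * j + pl * (dw[2] - 1);
        if (G.bc[4] == BC_SLIP || G.bc[4] == BC_INFLOW) W[lo] = 0.0;
        else if (G.bc[4] == BC_OUTFLOW) W[lo] = W[lo + pl];
        if (G.bc[5] == BC_SLIP || G.bc[5] == BC_INFLOW) W[hi] = 0.0;
        else if (G.bc[5] == BC_OUTFLOW) W[hi] = W[hi - pl];
      }
  }
  return List::create(_["u"] = u, _["v"] = v, _["w"] = w);
}

// subtract dt * grad(p) from interior faces
// [[Rcpp::export]]
List cpp_project(NumericVector u, NumericVector v, NumericVector w,
                 NumericVector p, List grid, double dt) {
  Grid G = make_grid(grid);
  int nx = G.ax[0].n, ny = G.ax[1].n, nz = G.ax[2].n;
  const double* P = p.begin();
  NumericVector* arrs[3] = {&u, &v, &w};
  for (int c = 0; c < 3; ++c) {
    int dims[3]; comp_dims(G, c, dims);
    double* Q = arrs[c]->begin();
    const Axis& a = G.ax[c];
    int lo = a.periodic ? 0 : 1;
    int hi = a.periodic ? a.n : dims[c] - 1;
    int i[3];
    int nlim[3] = {dims[0], dims[1], dims[2]};
    nlim[c] = hi;
    for (i[2] = (c == 2 ? lo : 0); i[2] < nlim[2]; ++i[2])
      for (i[1] = (c == 1 ? lo : 0); i[1] < nlim[1]; ++i[1])
        for (i[0] = (c == 0 ? lo : 0); i[0] < nlim[0]; ++i[0]) {
          int ic[3] = {i[0], i[1], i[2]};  // cell on + side of the face
          int im[3] = {i[0], i[1], i[2]};
          im[c] -= 1;
          if (im[c] < 0) im[c] = a.n - 1;  // periodic wrap
          double pp = P[ic[0] + (size_t)nx * (ic[1] + (size_t)ny * ic[2])];
          double pm = P[im[0] + (size_t)nx * (im[1] + (size_t)ny * im[2])];
          Q[i[0] + (size_t)dims[0] * (i[1] + (size_t)dims[1] * i[2])] -=
            dt * (pp - pm) / a.cdist(i[c]);
        }
  }
  return List::create(_["u"] = u, _["v"] = v, _["w"] = w);
}

// ----------------------------------------------------------------------
// multigrid Poisson solver (cell-centred, Neumann/periodic BCs)
// ----------------------------------------------------------------------

struct MGLevel {
  int n[3];
  std::vector<double> f[3];          // face coords per axis
  std::vector<double> am[3], ap[3];  // 1D stencil coefficient arrays
  std::vector<int> child_start[3], child_count[3];
  // trilinear prolongation maps (indexed by PARENT cell index per axis)
  std::vector<int> pc0[3], pc1[3];
  std::vector<double> pw[3];
  std::vector<double> p, r, rhs;
  bool periodic[3];
  size_t ncell() const { return (size_t)n[0] * n[1] * n[2]; }
};

static void level_coeffs(MGLevel& L) {
  for (int d = 0; d < 3; ++d) {
    int n = L.n[d];
    Axis a; a.n = n; a.periodic = L.periodic[d]; a.f = L.f[d];
    a.c.resize(n);
    for (int i = 0; i < n; ++i) a.c[i] = 0.5 * (a.f[i] + a.f[i + 1]);
    L.am[d].resize(n); L.ap[d].resize(n);
    for (int i = 0; i < n; ++i) {
      double dx = a.dx(i);
      double cm = a.cdist(i), cp = a.cdist(i + 1);
      L.am[d][i] = 1.0 / (dx * cm);
      L.ap[d][i] = 1.0 / (dx * cp);
      if (!a.periodic) {
        if (i == 0) L.am[d][i] = 0.0;        // Neumann
        if (i == n - 1) L.ap[d][i] = 0.0;
      }
    }
  }
}

// per-axis neighbour offsets (branch-free: boundary coefficients are zero,
// so wrapped offsets are only ever multiplied by zero when non-periodic)
struct MGOffsets {
  std::vector<ptrdiff_t> om[3], op[3];
  void build(const MGLevel& L) {
    const ptrdiff_t str[3] = {1, (ptrdiff_t)L.n[0], (ptrdiff_t)L.n[0] * L.n[1]};
    for (int d = 0; d < 3; ++d) {
      int n = L.n[d];
      om[d].resize(n); op[d].resize(n);
      for (int i = 0; i < n; ++i) {
        om[d][i] = (i == 0) ? str[d] * (n - 1) : -str[d];
        op[d][i] = (i == n - 1) ? -str[d] * (n - 1) : str[d];
      }
    }
  }
};

// residual r = rhs - A p
static void mg_residual(MGLevel& L, const MGOffsets& O) {
  int nx = L.n[0], ny = L.n[1], nz = L.n[2];
  const double* p = L.p.data();
  const double* rhs = L.rhs.data();
  double* r = L.r.data();
  for (int k = 0; k < nz; ++k) {
    double am2 = L.am[2][k], ap2 = L.ap[2][k];
    ptrdiff_t om2 = O.om[2][k], op2 = O.op[2][k];
    for (int j = 0; j < ny; ++j) {
      double am1 = L.am[1][j], ap1 = L.ap[1][j];
      ptrdiff_t om1 = O.om[1][j], op1 = O.op[1][j];
      size_t row = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        size_t id = i + row;
        double am0 = L.am[0][i], ap0 = L.ap[0][i];
        double s = am0 * p[id + O.om[0][i]] + ap0 * p[id + O.op[0][i]] +
                   am1 * p[id + om1] + ap1 * p[id + op1] +
                   am2 * p[id + om2] + ap2 * p[id + op2];
        double diag = am0 + ap0 + am1 + ap1 + am2 + ap2;
        r[id] = rhs[id] - (s - diag * p[id]);
      }
    }
  }
}

// solve tridiagonal (optionally cyclic) system in place: sub a, diag b,
// super c, rhs r -> solution in r.  Workspaces cp, u, z of length n.
static void thomas(int n, const double* a, const double* b, const double* c,
                   double* r, double* cp, bool cyclic, double* u, double* z) {
  if (!cyclic || n < 3) {
    // plain Thomas (ignore cyclic corners for tiny n)
    cp[0] = c[0] / b[0];
    r[0] = r[0] / b[0];
    for (int i = 1; i < n; ++i) {
      double m = 1.0 / (b[i] - a[i] * cp[i - 1]);
      cp[i] = c[i] * m;
      r[i] = (r[i] - a[i] * r[i - 1]) * m;
    }
    for (int i = n - 2; i >= 0; --i) r[i] -= cp[i] * r[i + 1];
    return;
  }
  // Sherman-Morrison for the cyclic corners a[0] (to n-1) and c[n-1] (to 0)
  double alpha = a[0], beta = c[n - 1];
  double gamma = -b[0];
  std::vector<double> bb(b, b + n);
  bb[0] -= gamma;
  bb[n - 1] -= alpha * beta / gamma;
  for (int i = 0; i < n; ++i) { u[i] = 0.0; }
  u[0] = gamma; u[n - 1] = beta;
  // solve with modified diagonal for both r and u
  cp[0] = c[0] / bb[0];
  r[0] /= bb[0]; z[0] = u[0] / bb[0];
  for (int i = 1; i < n; ++i) {
    double m = 1.0 / (bb[i] - a[i] * cp[i - 1]);
    cp[i] = c[i] * m;
    r[i] = (r[i] - a[i] * r[i - 1]) * m;
    z[i] = (u[i] - a[i] * z[i - 1]) * m;
  }
  for (int i = n - 2; i >= 0; --i) {
    r[i] -= cp[i] * r[i + 1];
    z[i] -= cp[i] * z[i + 1];
  }
  double fact = (r[0] + alpha * r[n - 1] / gamma) /
                (1.0 + z[0] + alpha * z[n - 1] / gamma);
  for (int i = 0; i < n; ++i) r[i] -= fact * z[i];
}

// red-black point Gauss-Seidel smoother
static void mg_smooth(MGLevel& L, const MGOffsets& O, int sweeps) {
  int nx = L.n[0], ny = L.n[1], nz = L.n[2];
  double* p = L.p.data();
  const double* rhs = L.rhs.data();
  for (int sw = 0; sw < sweeps; ++sw)
    for (int color = 0; color < 2; ++color)
      for (int k = 0; k < nz; ++k) {
        double am2 = L.am[2][k], ap2 = L.ap[2][k];
        ptrdiff_t om2 = O.om[2][k], op2 = O.op[2][k];
        for (int j = 0; j < ny; ++j) {
          double am1 = L.am[1][j], ap1 = L.ap[1][j];
          ptrdiff_t om1 = O.om[1][j], op1 = O.op[1][j];
          size_t row = (size_t)nx * (j + (size_t)ny * k);
          for (int i = (j + k + color) & 1; i < nx; i += 2) {
            size_t id = i + row;
            double am0 = L.am[0][i], ap0 = L.ap[0][i];
            double s = am0 * p[id + O.om[0][i]] + ap0 * p[id + O.op[0][i]] +
                       am1 * p[id + om1] + ap1 * p[id + op1] +
                       am2 * p[id + om2] + ap2 * p[id + op2];
            double diag = am0 + ap0 + am1 + ap1 + am2 + ap2;
            if (diag > 0.0) p[id] = (s - rhs[id]) / diag;
          }
        }
      }
}

// alternating-direction line Gauss-Seidel: robust for the anisotropic
// cells of stretched grids, where point smoothing stalls
static void mg_line_smooth(MGLevel& L, int sweeps) {
  int n[3] = {L.n[0], L.n[1], L.n[2]};
  const size_t str[3] = {1, (size_t)n[0], (size_t)n[0] * n[1]};
  int nmax = std::max(n[0], std::max(n[1], n[2]));
  std::vector<double> a(nmax), b(nmax), c(nmax), r(nmax), cp(nmax), u(nmax), z(nmax);
  double* p = L.p.data();
  const double* rhs = L.rhs.data();
  for (int sw = 0; sw < sweeps; ++sw)
    for (int d = 0; d < 3; ++d) {
      int o1 = (d + 1) % 3, o2 = (d + 2) % 3;
      bool cyc = L.periodic[d];
      for (int k = 0; k < n[o2]; ++k)
        for (int j = 0; j < n[o1]; ++j) {
          size_t base = str[o1] * j + str[o2] * k;
          for (int i = 0; i < n[d]; ++i) {
            size_t id = base + str[d] * i;
            double am_d = L.am[d][i], ap_d = L.ap[d][i];
            double am1 = L.am[o1][j], ap1 = L.ap[o1][j];
            double am2 = L.am[o2][k], ap2 = L.ap[o2][k];
            double diag = am_d + ap_d + am1 + ap1 + am2 + ap2;
            double s = 0.0;
            if (am1 != 0.0)
              s += am1 * p[(j == 0) ? id + str[o1] * (n[o1] - 1) : id - str[o1]];
            if (ap1 != 0.0)
              s += ap1 * p[(j == n[o1] - 1) ? id - str[o1] * (n[o1] - 1) : id + str[o1]];
            if (am2 != 0.0)
              s += am2 * p[(k == 0) ? id + str[o2] * (n[o2] - 1) : id - str[o2]];
            if (ap2 != 0.0)
              s += ap2 * p[(k == n[o2] - 1) ? id - str[o2] * (n[o2] - 1) : id + str[o2]];
            a[i] = am_d; c[i] = ap_d; b[i] = -diag;
            r[i] = rhs[id] - s;
            if (diag == 0.0) { b[i] = -1.0; r[i] = -p[id]; a[i] = c[i] = 0.0; }
          }
          thomas(n[d], a.data(), b.data(), c.data(), r.data(), cp.data(),
                 cyc, u.data(), z.data());
          for (int i = 0; i < n[d]; ++i) p[base + str[d] * i] = r[i];
        }
    }
}


static std::vector<MGLevel> mg_build(const Grid& G) {
  std::vector<MGLevel> lev;
  MGLevel L0;
  for (int d = 0; d < 3; ++d) {
    L0.n[d] = G.ax[d].n;
    L0.f[d] = G.ax[d].f;
    L0.periodic[d] = G.ax[d].periodic;
  }
  lev.push_back(L0);
  while ((int)lev.size() < 12) {
    MGLevel& F = lev.back();
    if (std::min(std::min(F.n[0], F.n[1]), F.n[2]) < 6) break;
    MGLevel C;
    for (int d = 0; d < 3; ++d) {
      C.periodic[d] = F.periodic[d];
      int nf = F.n[d];
      int nc = nf / 2;               // last coarse cell absorbs 3 fine if odd
      C.n[d] = nc;
      C.f[d].resize(nc + 1);
      C.child_start[d].resize(nc);
      C.child_count[d].resize(nc);
      for (int i = 0; i < nc; ++i) {
        C.child_start[d][i] = 2 * i;
        C.child_count[d][i] = (i == nc - 1) ? nf - 2 * i : 2;
      }
      for (int i = 0; i < nc; ++i) C.f[d][i] = F.f[d][2 * i];
      C.f[d][nc] = F.f[d][nf];
      // trilinear prolongation weights for every parent (fine) cell
      std::vector<double> xcF(nf), xcC(nc);
      for (int i = 0; i < nf; ++i) xcF[i] = 0.5 * (F.f[d][i] + F.f[d][i + 1]);
      for (int i = 0; i < nc; ++i) xcC[i] = 0.5 * (C.f[d][i] + C.f[d][i + 1]);
      C.pc0[d].resize(nf); C.pc1[d].resize(nf); C.pw[d].resize(nf);
      double period = F.f[d][nf] - F.f[d][0];
      for (int i = 0; i < nf; ++i) {
        double x = xcF[i];
        if (x <= xcC[0]) {
          if (C.periodic[d]) {
            C.pc0[d][i] = nc - 1; C.pc1[d][i] = 0;
            double gap = xcC[0] - (xcC[nc - 1] - period);
            C.pw[d][i] = (x - (xcC[nc - 1] - period)) / gap;
          } else { C.pc0[d][i] = 0; C.pc1[d][i] = 0; C.pw[d][i] = 0.0; }
        } else if (x >= xcC[nc - 1]) {
          if (C.periodic[d]) {
            C.pc0[d][i] = nc - 1; C.pc1[d][i] = 0;
            double gap = (xcC[0] + period) - xcC[nc - 1];
            C.pw[d][i] = (x - xcC[nc - 1]) / gap;
          } else { C.pc0[d][i] = nc - 1; C.pc1[d][i] = nc - 1; C.pw[d][i] = 0.0; }
        } else {
          int j = 0;
          while (j < nc - 2 && xcC[j + 1] <= x) ++j;
          C.pc0[d][i] = j; C.pc1[d][i] = j + 1;
          C.pw[d][i] = (x - xcC[j]) / (xcC[j + 1] - xcC[j]);
        }
      }
    }
    lev.push_back(C);
  }
  for (auto& L : lev) {
    level_coeffs(L);
    L.p.assign(L.ncell(), 0.0);
    L.r.assign(L.ncell(), 0.0);
    L.rhs.assign(L.ncell(), 0.0);
  }
  return lev;
}

static void mg_vcycle(std::vector<MGLevel>& lev, std::vector<MGOffsets>& offs,
                      size_t l, int nsmooth = 2, int gamma = 1) {
  MGLevel& L = lev[l];
  if (l + 1 == lev.size()) {
    mg_smooth(L, offs[l], 40);
    mg_line_smooth(L, 4);
    return;
  }
  mg_smooth(L, offs[l], nsmooth);
  mg_residual(L, offs[l]);
  MGLevel& C = lev[l + 1];
  // restriction: volume-weighted average of residual
  std::fill(C.p.begin(), C.p.end(), 0.0);
  int nxc = C.n[0], nyc = C.n[1], nzc = C.n[2];
  int nxf = L.n[0], nyf = L.n[1];
  for (int kc = 0; kc < nzc; ++kc)
    for (int jc = 0; jc < nyc; ++jc)
      for (int ic = 0; ic < nxc; ++ic) {
        double num = 0.0, den = 0.0;
        for (int dk = 0; dk < C.child_count[2][kc]; ++dk)
          for (int dj = 0; dj < C.child_count[1][jc]; ++dj)
            for (int di = 0; di < C.child_count[0][ic]; ++di) {
              int i = C.child_start[0][ic] + di;
              int j = C.child_start[1][jc] + dj;
              int k = C.child_start[2][kc] + dk;
              double vol = (L.f[0][i + 1] - L.f[0][i]) * (L.f[1][j + 1] - L.f[1][j]) *
                           (L.f[2][k + 1] - L.f[2][k]);
              num += vol * L.r[i + (size_t)nxf * (j + (size_t)nyf * k)];
              den += vol;
            }
        C.rhs[ic + (size_t)nxc * (jc + (size_t)nyc * kc)] = num / den;
      }
  for (int g = 0; g < gamma; ++g)
    mg_vcycle(lev, offs, l + 1, nsmooth, gamma);
  // prolongation: trilinear interpolation of the coarse correction
  {
    const double* cp = C.p.data();
    double* fp = L.p.data();
    for (int k = 0; k < L.n[2]; ++k) {
      int k0 = C.pc0[2][k], k1 = C.pc1[2][k]; double wk = C.pw[2][k];
      for (int j = 0; j < L.n[1]; ++j) {
        int j0 = C.pc0[1][j], j1 = C.pc1[1][j]; double wj = C.pw[1][j];
        size_t row = (size_t)nxf * (j + (size_t)nyf * k);
        size_t cj0k0 = (size_t)nxc * (j0 + (size_t)nyc * k0);
        size_t cj1k0 = (size_t)nxc * (j1 + (size_t)nyc * k0);
        size_t cj0k1 = (size_t)nxc * (j0 + (size_t)nyc * k1);
        size_t cj1k1 = (size_t)nxc * (j1 + (size_t)nyc * k1);
        for (int i = 0; i < L.n[0]; ++i) {
          int i0 = C.pc0[0][i], i1 = C.pc1[0][i]; double wi = C.pw[0][i];
          double c00 = (1 - wi) * cp[i0 + cj0k0] + wi * cp[i1 + cj0k0];
          double c10 = (1 - wi) * cp[i0 + cj1k0] + wi * cp[i1 + cj1k0];
          double c01 = (1 - wi) * cp[i0 + cj0k1] + wi * cp[i1 + cj0k1];
          double c11 = (1 - wi) * cp[i0 + cj1k1] + wi * cp[i1 + cj1k1];
          fp[i + row] += (1 - wk) * ((1 - wj) * c00 + wj * c10) +
                         wk * ((1 - wj) * c01 + wj * c11);
        }
      }
    }
  }
  mg_smooth(L, offs[l], nsmooth);
}

struct MGContext {
  std::vector<MGLevel> lev;
  std::vector<MGOffsets> offs;
};

// [[Rcpp::export]]
SEXP cpp_mg_setup(List grid) {
  Grid G = make_grid(grid);
  XPtr<MGContext> ctx(new MGContext, true);
  ctx->lev = mg_build(G);
  ctx->offs.resize(ctx->lev.size());
  for (size_t l = 0; l < ctx->lev.size(); ++l) ctx->offs[l].build(ctx->lev[l]);
  return ctx;
}

// [[Rcpp::export]]
List cpp_poisson_mg(NumericVector rhs, List grid, double tol = 1e-7,
                    int max_cycles = 60, Nullable<NumericVector> p0 = R_NilValue,
                    SEXP ctx_ptr = R_NilValue, int nsmooth = 3, int gamma = 1) {
  MGContext local;
  MGContext* ctx = &local;
  if (ctx_ptr != R_NilValue) {
    XPtr<MGContext> xp(ctx_ptr);
    ctx = xp.get();
  } else {
    Grid G = make_grid(grid);
    local.lev = mg_build(G);
    local.offs.resize(local.lev.size());
    for (size_t l = 0; l < local.lev.size(); ++l) local.offs[l].build(local.lev[l]);
  }
  std::vector<MGLevel>& lev = ctx->lev;
  std::vector<MGOffsets>& offs = ctx->offs;
  MGLevel& L = lev[0];
  std::fill(L.p.begin(), L.p.end(), 0.0);
  size_t n = L.ncell();
  if ((size_t)rhs.size() != n) stop("cpp_poisson_mg: rhs size mismatch");
  if (p0.isNotNull()) {
    NumericVector pinit(p0);
    if ((size_t)pinit.size() == n)
      std::copy(pinit.begin(), pinit.end(), L.p.begin());
  }

  // compatibility: all-Neumann/periodic problems need a zero-mean rhs
  double vsum = 0.0, rsum = 0.0;
  std::vector<double> vol(n);
  {
    int nx = L.n[0], ny = L.n[1], nz = L.n[2];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = i + (size_t)nx * (j + (size_t)ny * k);
          vol[id] = (L.f[0][i + 1] - L.f[0][i]) * (L.f[1][j + 1] - L.f[1][j]) *
                    (L.f[2][k + 1] - L.f[2][k]);
          vsum += vol[id]; rsum += vol[id] * rhs[id];
        }
  }
  double correction = rsum / vsum;
  for (size_t i = 0; i < n; ++i) L.rhs[i] = rhs[i] - correction;

  double rhs_norm = 0.0;
  for (size_t i = 0; i < n; ++i) rhs_norm += L.rhs[i] * L.rhs[i];
  rhs_norm = std::sqrt(rhs_norm / n);
  NumericVector hist(max_cycles);
  int it = 0;
  double relres = 0.0;
  // conjugate gradients preconditioned by one multigrid V-cycle: the
  // V-cycle alone degrades on the anisotropic stretched cells, CG
  // stabilises it at negligible extra cost
  if (rhs_norm > 0.0) {
    std::vector<double> bvec(L.rhs), x(L.p), r(n), z(n), dvec(n), q(n);
    double vtot = 0.0;
    for (size_t i = 0; i < n; ++i) vtot += vol[i];
    mg_residual(L, offs[0]);          // L.r = b - A x0
    std::copy(L.r.begin(), L.r.end(), r.begin());
    double rz_old = 0.0;
    for (it = 0; it < max_cycles; ++it) {
      double rn = 0.0;
      for (size_t i = 0; i < n; ++i) rn += r[i] * r[i];
      relres = std::sqrt(rn / n) / rhs_norm;
      hist[it] = relres;
      if (relres <= tol) break;
      // z = M^{-1} r via one V-cycle from zero
      std::copy(r.begin(), r.end(), L.rhs.begin());
      std::fill(L.p.begin(), L.p.end(), 0.0);
      mg_vcycle(lev, offs, 0, nsmooth, gamma);
      double zmean = 0.0;
      for (size_t i = 0; i < n; ++i) zmean += vol[i] * L.p[i];
      zmean /= vtot;
      for (size_t i = 0; i < n; ++i) z[i] = L.p[i] - zmean;
      // the assembled operator is the negative-definite Laplacian, so the
      // CG curvature products are negative; ratios in alpha/beta cancel
      double rz = 0.0;
      for (size_t i = 0; i < n; ++i) rz += r[i] * z[i];
      if (!(rz < 0.0)) {   // fall back to (sign-consistent) steepest descent
        for (size_t i = 0; i < n; ++i) z[i] = -r[i];
        rz = -rn;
      }
      if (it == 0) std::copy(z.begin(), z.end(), dvec.begin());
      else {
        double beta = rz / rz_old;
        for (size_t i = 0; i < n; ++i) dvec[i] = z[i] + beta * dvec[i];
      }
      // q = A d (via the residual of the zero problem)
      std::copy(dvec.begin(), dvec.end(), L.p.begin());
      std::fill(L.rhs.begin(), L.rhs.end(), 0.0);
      mg_residual(L, offs[0]);
      for (size_t i = 0; i < n; ++i) q[i] = -L.r[i];
      double dq = 0.0;
      for (size_t i = 0; i < n; ++i) dq += dvec[i] * q[i];
      if (!(dq < 0.0)) break;
      double alpha = rz / dq;
      for (size_t i = 0; i < n; ++i) { x[i] += alpha * dvec[i]; r[i] -= alpha * q[i]; }
      rz_old = rz;
    }
    std::copy(x.begin(), x.end(), L.p.begin());
    std::copy(bvec.begin(), bvec.end(), L.rhs.begin());
  }
  // gauge: zero-mean solution
  double pm = 0.0;
  for (size_t i = 0; i < n; ++i) pm += vol[i] * L.p[i];
  pm /= vsum;
  NumericVector p(n);
  for (size_t i = 0; i < n; ++i) p[i] = L.p[i] - pm;
  p.attr("dim") = IntegerVector::create(L.n[0], L.n[1], L.n[2]);
  return List::create(_["p"] = p, _["iterations"] = it, _["relres"] = relres,
                      _["residual_history"] = head(hist, std::max(it, 1)),
                      _["compat_correction"] = correction);
}

// ----------------------------------------------------------------------
// immersed-boundary geometry kernels
// ----------------------------------------------------------------------

// ray-parity solid classification of tensor-product query points
// (ray cast along +x for each (y, z) column)
// [[Rcpp::export]]
LogicalVector cpp_classify_solid(NumericVector xq, NumericVector yq, NumericVector zq,
                                 NumericMatrix nodes, IntegerMatrix tris) {
  int nx = xq.size(), ny = yq.size(), nz = zq.size();
  int ntri = tris.nrow();
  LogicalVector out((size_t)nx * ny * nz);
  // tiny jitter avoids rays hitting triangle edges exactly
  const double eps = 1e-9;
  std::vector<std::vector<double>> cross((size_t)ny * nz);
  for (int t = 0; t < ntri; ++t) {
    double ax = nodes(tris(t, 0) - 1, 0), ay = nodes(tris(t, 0) - 1, 1), az = nodes(tris(t, 0) - 1, 2);
    double bx = nodes(tris(t, 1) - 1, 0), by = nodes(tris(t, 1) - 1, 1), bz = nodes(tris(t, 1) - 1, 2);
    double cx = nodes(tris(t, 2) - 1, 0), cy = nodes(tris(t, 2) - 1, 1), cz = nodes(tris(t, 2) - 1, 2);
    double ylo = std::min(ay, std::min(by, cy)), yhi = std::max(ay, std::max(by, cy));
    double zlo = std::min(az, std::min(bz, cz)), zhi = std::max(az, std::max(bz, cz));
    for (int k = 0; k < nz; ++k) {
      double z = zq[k] + eps;
      if (z < zlo || z > zhi) continue;
      for (int j = 0; j < ny; ++j) {
        double y = yq[j] + eps * 1.3;
        if (y < ylo || y > yhi) continue;
        // 2D point-in-triangle in (y,z); if inside, x of the intersection
        double d1 = (by - ay) * (z - az) - (bz - az) * (y - ay);
        double d2 = (cy - by) * (z - bz) - (cz - bz) * (y - by);
        double d3 = (ay - cy) * (z - cz) - (az - cz) * (y - cy);
        bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
        bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
        if (neg && pos) continue;
        double denom = d1 + d2 + d3;
        if (std::fabs(denom) < 1e-300) continue;
        double w1 = d2 / denom, w2 = d3 / denom, w3 = d1 / denom;
        double xint = w1 * ax + w2 * bx + w3 * cx;
        cross[j + (size_t)ny * k].push_back(xint);
      }
    }
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      std::vector<double>& cc = cross[j + (size_t)ny * k];
      if (cc.empty()) continue;
      std::sort(cc.begin(), cc.end());
      for (int i = 0; i < nx; ++i) {
        // parity of crossings beyond xq[i]
        size_t m = std::upper_bound(cc.begin(), cc.end(), xq[i]) - cc.begin();
        if ((cc.size() - m) % 2 == 1)
          out[i + (size_t)nx * (j + (size_t)ny * k)] = true;
      }
    }
  return out;
}

// closest point on triangle (Ericson, Real-Time Collision Detection)
static void closest_on_tri(const double p[3], const double a[3], const double b[3],
                           const double c[3], double out[3], double bary[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; bary[0] = 1; bary[1] = 0; bary[2] = 0; return; }
  double bp[3]; for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; bary[0] = 0; bary[1] = 1; bary[2] = 0; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + t * ab[i];
    bary[0] = 1 - t; bary[1] = t; bary[2] = 0; return;
  }
  double cp[3]; for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; bary[0] = 0; bary[1] = 0; bary[2] = 1; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + t * ac[i];
    bary[0] = 1 - t; bary[1] = 0; bary[2] = t; return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + t * (c[i] - b[i]);
    bary[0] = 0; bary[1] = 1 - t; bary[2] = t; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
}

// membrane classification: tensor-grid points within `support` of the
// surface get the velocity of the nearest surface point.  Returns only the
// hit points: 1-based linear indices, distances and target velocities.
// [[Rcpp::export]]
List cpp_classify_membrane(NumericVector xq, NumericVector yq, NumericVector zq,
                           NumericMatrix nodes, NumericMatrix vels,
                           IntegerMatrix tris, double support) {
  int nx = xq.size(), ny = yq.size(), nz = zq.size();
  size_t npts = (size_t)nx * ny * nz;
  std::vector<double> best(npts, std::numeric_limits<double>::infinity());
  std::vector<double> tu(npts), tv(npts), tw(npts);
  std::vector<size_t> hits;
  int ntri = tris.nrow();
  for (int t = 0; t < ntri; ++t) {
    double a[3], b[3], c[3];
    for (int i = 0; i < 3; ++i) {
      a[i] = nodes(tris(t, 0) - 1, i);
      b[i] = nodes(tris(t, 1) - 1, i);
      c[i] = nodes(tris(t, 2) - 1, i);
    }
    double lo[3], hi[3];
    for (int i = 0; i < 3; ++i) {
      lo[i] = std::min(a[i], std::min(b[i], c[i])) - support;
      hi[i] = std::max(a[i], std::max(b[i], c[i])) + support;
    }
    int i0 = std::lower_bound(xq.begin(), xq.end(), lo[0]) - xq.begin();
    int i1 = std::upper_bound(xq.begin(), xq.end(), hi[0]) - xq.begin();
    int j0 = std::lower_bound(yq.begin(), yq.end(), lo[1]) - yq.begin();
    int j1 = std::upper_bound(yq.begin(), yq.end(), hi[1]) - yq.begin();
    int k0 = std::lower_bound(zq.begin(), zq.end(), lo[2]) - zq.begin();
    int k1 = std::upper_bound(zq.begin(), zq.end(), hi[2]) - zq.begin();
    for (int k = k0; k < k1; ++k)
      for (int j = j0; j < j1; ++j)
        for (int i = i0; i < i1; ++i) {
          double p[3] = {xq[i], yq[j], zq[k]};
          double q[3], bar[3];
          closest_on_tri(p, a, b, c, q, bar);
          double d = std::sqrt((p[0] - q[0]) * (p[0] - q[0]) +
                               (p[1] - q[1]) * (p[1] - q[1]) +
                               (p[2] - q[2]) * (p[2] - q[2]));
          size_t id = i + (size_t)nx * (j + (size_t)ny * k);
          if (d <= support && d < best[id]) {
            if (!std::isfinite(best[id])) hits.push_back(id);
            best[id] = d;
            int n0 = tris(t, 0) - 1, n1 = tris(t, 1) - 1, n2 = tris(t, 2) - 1;
            tu[id] = bar[0] * vels(n0, 0) + bar[1] * vels(n1, 0) + bar[2] * vels(n2, 0);
            tv[id] = bar[0] * vels(n0, 1) + bar[1] * vels(n1, 1) + bar[2] * vels(n2, 1);
            tw[id] = bar[0] * vels(n0, 2) + bar[1] * vels(n1, 2) + bar[2] * vels(n2, 2);
          }
        }
  }
  std::sort(hits.begin(), hits.end());
  int nh = hits.size();
  IntegerVector idx(nh);
  NumericVector dist(nh), ou(nh), ov(nh), ow(nh);
  for (int m = 0; m < nh; ++m) {
    size_t id = hits[m];
    idx[m] = (int)id + 1;
    dist[m] = best[id]; ou[m] = tu[id]; ov[m] = tv[id]; ow[m] = tw[id];
  }
  return List::create(_["idx"] = idx, _["dist"] = dist,
                      _["u"] = ou, _["v"] = ov, _["w"] = ow);
}

// ----------------------------------------------------------------------
// interpolation
// ----------------------------------------------------------------------

// linear interpolation weight lookup along sorted coords (clamped)
static inline void locate(const std::vector<double>& x, double q, int& i0, double& wgt) {
  int n = x.size();
  if (q <= x[0]) { i0 = 0; wgt = 0.0; return; }
  if (q >= x[n - 1]) { i0 = n - 2; wgt = 1.0; return; }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (x[mid] <= q) lo = mid; else hi = mid; }
  i0 = lo;
  wgt = (q - x[lo]) / (x[lo + 1] - x[lo]);
}

// trilinear sample of one staggered component at arbitrary points
static double sample_comp(const Grid& G, int comp, const Field& F,
                          double px, double py, double pz) {
  double p[3] = {px, py, pz};
  int base[3]; double w[3];
  for (int d = 0; d < 3; ++d) {
    const Axis& a = G.ax[d];
    std::vector<double> coords;
    if (d == comp) coords = a.f;  // faces (n+1); for periodic arrays face n wraps
    else coords.assign(a.c.begin(), a.c.end());
    int i0; double wt;
    locate(coords, p[d], i0, wt);
    base[d] = i0; w[d] = wt;
  }
  double s = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double wt = (di ? w[0] : 1 - w[0]) * (dj ? w[1] : 1 - w[1]) * (dk ? w[2] : 1 - w[2]);
        if (wt == 0.0) continue;
        s += wt * stag_val(G, comp, F, base[0] + di, base[1] + dj, base[2] + dk);
      }
  return s;
}

// [[Rcpp::export]]
NumericMatrix cpp_interp_velocity(NumericVector u, NumericVector v, NumericVector w,
                                  List grid, NumericMatrix points) {
  Grid G = make_grid(grid);
  const NumericVector* arrs[3] = {&u, &v, &w};
  Field F[3];
  for (int c = 0; c < 3; ++c) {
    int dims[3]; comp_dims(G, c, dims);
    F[c].a = arrs[c]->begin(); F[c].d0 = dims[0]; F[c].d1 = dims[1]; F[c].d2 = dims[2];
  }
  int np = points.nrow();
  NumericMatrix out(np, 3);
  for (int i = 0; i < np; ++i)
    for (int c = 0; c < 3; ++c)
      out(i, c) = sample_comp(G, c, F[c], points(i, 0), points(i, 1), points(i, 2));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_interp_center(NumericVector s, List grid, NumericMatrix points) {
  Grid G = make_grid(grid);
  int np = points.nrow();
  NumericVector out(np);
  int nx = G.ax[0].n, ny = G.ax[1].n;
  for (int ipt = 0; ipt < np; ++ipt) {
    int base[3]; double w[3];
    double p[3] = {points(ipt, 0), points(ipt, 1), points(ipt, 2)};
    for (int d = 0; d < 3; ++d) {
      std::vector<double> coords(G.ax[d].c.begin(), G.ax[d].c.end());
      locate(coords, p[d], base[d], w[d]);
    }
    double sv = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double wt = (di ? w[0] : 1 - w[0]) * (dj ? w[1] : 1 - w[1]) * (dk ? w[2] : 1 - w[2]);
          sv += wt * s[(base[0] + di) + (size_t)nx * ((base[1] + dj) + (size_t)ny * (base[2] + dk))];
        }
    out[ipt] = sv;
  }
  return out;
}

// cell-centre averaged velocity (for vortex diagnostics)
// [[Rcpp::export]]
List cpp_center_velocity(NumericVector u, NumericVector v, NumericVector w, List grid) {
  Grid G = make_grid(grid);
  const NumericVector* arrs[3] = {&u, &v, &w};
  Field F[3];
  for (int c = 0; c < 3; ++c) {
    int dims[3]; comp_dims(G, c, dims);
    F[c].a = arrs[c]->begin(); F[c].d0 = dims[0]; F[c].d1 = dims[1]; F[c].d2 = dims[2];
  }
  int nx = G.ax[0].n, ny = G.ax[1].n, nz = G.ax[2].n;
  NumericVector uc((size_t)nx * ny * nz), vc((size_t)nx * ny * nz), wc((size_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = i + (size_t)nx * (j + (size_t)ny * k);
        uc[id] = 0.5 * (face_val(G, 0, F[0], i, j, k) + face_val(G, 0, F[0], i + 1, j, k));
        vc[id] = 0.5 * (face_val(G, 1, F[1], j, i, k) + face_val(G, 1, F[1], j + 1, i, k));
        wc[id] = 0.5 * (face_val(G, 2, F[2], k, i, j) + face_val(G, 2, F[2], k + 1, i, j));
      }
  IntegerVector dm = IntegerVector::create(nx, ny, nz);
  uc.attr("dim") = dm; vc.attr("dim") = dm; wc.attr("dim") = dm;
  return List::create(_["u"] = uc, _["v"] = vc, _["w"] = wc);
}
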