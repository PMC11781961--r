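// Low-level computational kernels for the IB/FE solver:
//  - regularised delta-function force spreading and velocity interpolation
//    on the staggered (MAC) grid
//  - explicit advection-diffusion update and divergence/gradient stencils
// Layout: R column-major arrays; u (nx+1,ny,nz), v (nx,ny+1,nz),
// w (nx,ny,nz+1), cell-centred scalars (nx,ny,nz).  All lengths in cm,
// CGS units throughout.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- kernels --

// Peskin 4-point kernel
static inline double phi4(double r) {
  double a = std::fabs(r);
  if (a < 1.0)      return (3.0 - 2.0 * a + std::sqrt(1.0 + 4.0 * a - 4.0 * a * a)) / 8.0;
  else if (a < 2.0) return (5.0 - 2.0 * a - std::sqrt(-7.0 + 12.0 * a - 4.0 * a * a)) / 8.0;
  return 0.0;
}

// Peskin 3-point kernel
static inline double phi3(double r) {
  double a = std::fabs(r);
  if (a < 0.5)      return (1.0 + std::sqrt(1.0 - 3.0 * a * a)) / 3.0;
  else if (a < 1.5) return (5.0 - 3.0 * a - std::sqrt(1.0 - 3.0 * (1.0 - a) * (1.0 - a))) / 6.0;
  return 0.0;
}

// quintic B-spline (6-point support); reproduces constants and linears
static inline double phi6(double r) {
  double a = std::fabs(r);
  if (a >= 3.0) return 0.0;
  double s = std::pow(3.0 - a, 5);
  if (a < 2.0) s -= 6.0 * std::pow(2.0 - a, 5);
  if (a < 1.0) s += 15.0 * std::pow(1.0 - a, 5);
  return s / 120.0;
}

static inline double phi(double r, int fam) {
  switch (fam) {
  case 3: return phi3(r);
  case 6: return phi6(r);
  default: return phi4(r);
  }
}

static inline int support(int fam) { return fam == 3 ? 3 : (fam == 6 ? 6 : 4); }

// first index of the support window for grid coordinate g
static inline int base_index(double g, int fam) {
  if (fam == 3) return (int)std::floor(g + 0.5) - 1;
  if (fam == 6) return (int)std::floor(g) - 2;
  return (int)std::floor(g) - 1;
}

// [[Rcpp::export]]
NumericVector cpp_kernel_phi(NumericVector r, int family) {
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = phi(r[i], family);
  return out;
}

// ------------------------------------------------------------ spread/interp

struct StagSpec { double ox, oy, oz; int dx, dy, dz; };

// offsets (in cells) of the first sample of each staggered component and
// dimension increments relative to (nx,ny,nz)
static StagSpec stag_for(int comp, int /*nx*/, int /*ny*/, int /*nz*/) {
  // comp 0 = u (x-faces), 1 = v, 2 = w
  StagSpec s;
  if (comp == 0)      { s.ox = 0.0; s.oy = 0.5; s.oz = 0.5; s.dx = 1; s.dy = 0; s.dz = 0; }
  else if (comp == 1) { s.ox = 0.5; s.oy = 0.0; s.oz = 0.5; s.dx = 0; s.dy = 1; s.dz = 0; }
  else                { s.ox = 0.5; s.oy = 0.5; s.oz = 0.0; s.dx = 0; s.dy = 0; s.dz = 1; }
  return s;
}

static inline int clampi(int i, int n, bool periodic, bool &clamped) {
  if (periodic) {
    int m = i % n; if (m < 0) m += n; return m;
  }
  if (i < 0) { clamped = true; return 0; }
  if (i >= n) { clamped = true; return n - 1; }
  return i;
}

// Spread Lagrangian quantities q (n x 3, already multiplied by nodal
// reference weights, dyn) onto the three staggered force components.
// Returns list(fx, fy, fz, n_clamped).  Division by h^3 converts the
// quadrature of the delta integral into a force density per unit volume.
// [[Rcpp::export]]
List cpp_spread(NumericMatrix pos, NumericMatrix q,
                int nx, int ny, int nz, double h,
                int family, bool periodic) {
  const int ns = support(family);
  const double h3 = h * h * h;
  List out(4);
  int n_clamped = 0;
  for (int comp = 0; comp < 3; ++comp) {
    StagSpec st = stag_for(comp, nx, ny, nz);
    int mx = nx + (periodic ? 0 : st.dx);
    int my = ny + (periodic ? 0 : st.dy);
    int mz = nz + (periodic ? 0 : st.dz);
    NumericVector f(Dimension(mx, my, mz));
    double *fp = REAL(f);
    for (int n = 0; n < pos.nrow(); ++n) {
      double val = q(n, comp);
      if (val == 0.0) continue;
      double gx = pos(n, 0) / h - st.ox;
      double gy = pos(n, 1) / h - st.oy;
      double gz = pos(n, 2) / h - st.oz;
      int ix0 = base_index(gx, family);
      int iy0 = base_index(gy, family);
      int iz0 = base_index(gz, family);
      double wx[6], wy[6], wz[6];
      for (int a = 0; a < ns; ++a) {
        wx[a] = phi(gx - (ix0 + a), family);
        wy[a] = phi(gy - (iy0 + a), family);
        wz[a] = phi(gz - (iz0 + a), family);
      }
      bool cl = false;
      for (int c = 0; c < ns; ++c) {
        if (wz[c] == 0.0) continue;
        int kz = clampi(iz0 + c, mz, periodic, cl);
        for (int b = 0; b < ns; ++b) {
          if (wy[b] == 0.0) continue;
          int ky = clampi(iy0 + b, my, periodic, cl);
          double wzy = wz[c] * wy[b] * val / h3;
          for (int a = 0; a < ns; ++a) {
            if (wx[a] == 0.0) continue;
            int kx = clampi(ix0 + a, mx, periodic, cl);
            fp[kx + (R_xlen_t)mx * (ky + (R_xlen_t)my * kz)] += wx[a] * wzy;
          }
        }
      }
      if (cl) ++n_clamped;
    }
    out[comp] = f;
  }
  out[3] = n_clamped;
  out.names() = CharacterVector::create("fx", "fy", "fz", "n_clamped");
  return out;
}

// Interpolate staggered velocity to Lagrangian positions; returns n x 3.
// [[Rcpp::export]]
List cpp_interp(NumericVector u, NumericVector v, NumericVector w,
                NumericMatrix pos, int nx, int ny, int nz, double h,
                int family, bool periodic) {
  const int ns = support(family);
  NumericMatrix U(pos.nrow(), 3);
  const double *fields[3] = { REAL(u), REAL(v), REAL(w) };
  int n_clamped = 0;
  for (int comp = 0; comp < 3; ++comp) {
    StagSpec st = stag_for(comp, nx, ny, nz);
    int mx = nx + (periodic ? 0 : st.dx);
    int my = ny + (periodic ? 0 : st.dy);
    int mz = nz + (periodic ? 0 : st.dz);
    const double *fp = fields[comp];
    for (int n = 0; n < pos.nrow(); ++n) {
      double gx = pos(n, 0) / h - st.ox;
      double gy = pos(n, 1) / h - st.oy;
      double gz = pos(n, 2) / h - st.oz;
      int ix0 = base_index(gx, family);
      int iy0 = base_index(gy, family);
      int iz0 = base_index(gz, family);
      double wx[6], wy[6], wz[6];
      int kx[6], ky[6], kz[6];
      bool cl = false;
      for (int a = 0; a < ns; ++a) {
        wx[a] = phi(gx - (ix0 + a), family);
        wy[a] = phi(gy - (iy0 + a), family);
        wz[a] = phi(gz - (iz0 + a), family);
        kx[a] = wx[a] != 0.0 ? clampi(ix0 + a, mx, periodic, cl) : 0;
        ky[a] = wy[a] != 0.0 ? clampi(iy0 + a, my, periodic, cl) : 0;
        kz[a] = wz[a] != 0.0 ? clampi(iz0 + a, mz, periodic, cl) : 0;
      }
      double acc = 0.0;
      for (int c = 0; c < ns; ++c) {
        if (wz[c] == 0.0) continue;
        for (int b = 0; b < ns; ++b) {
          if (wy[b] == 0.0) continue;
          const double wzy = wz[c] * wy[b];
          const double *row = fp + (R_xlen_t)mx * (ky[b] + (R_xlen_t)my * kz[c]);
          double s = 0.0;
          for (int a = 0; a < ns; ++a) s += wx[a] * row[kx[a]];
          acc += wzy * s;
        }
      }
      U(n, comp) = acc;
      if (cl) ++n_clamped;
    }
  }
  return List::create(_["U"] = U, _["n_clamped"] = n_clamped);
}

// ------------------------------------------------------------ fluid stencils

// index helpers with zero-normal-gradient (clamp) or periodic closure
static inline int idx3(int i, int j, int k, int mx, int my) {
  return i + mx * (j + (R_xlen_t)my * k);
}
static inline int wrapc(int i, int n, bool periodic) {
  if (periodic) { int m = i % n; if (m < 0) m += n; return m; }
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// advection (centred, non-conservative) + diffusion + body force for one
// staggered component; in periodic mode all three components share dims
// (nx,ny,nz).
static void adv_diff_comp(const double *u, const double *v, const double *w,
                          const double *f, double *out, int comp,
                          int nx, int ny, int nz, double h, double dt,
                          double rho, double mu, bool periodic, bool upwind) {
  StagSpec st = stag_for(comp, nx, ny, nz);
  const int mx = nx + (periodic ? 0 : st.dx);
  const int my = ny + (periodic ? 0 : st.dy);
  const int mz = nz + (periodic ? 0 : st.dz);
  // dims of the other two fields
  const int ux = nx + (periodic ? 0 : 1), uy = ny, /*uz = nz,*/
            vx = nx, vy = ny + (periodic ? 0 : 1),
            wx_ = nx, wy_ = ny;
  const double nu = mu / rho;
  const double inv2h = 1.0 / (2.0 * h), invh2 = 1.0 / (h * h);
  const double *self = comp == 0 ? u : (comp == 1 ? v : w);

  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        const int id = idx3(i, j, k, mx, my);
        const double uc = self[id];
        // neighbours of self field (clamped => one-sided zero gradient)
        const double sxm = self[idx3(wrapc(i - 1, mx, periodic), j, k, mx, my)];
        const double sxp = self[idx3(wrapc(i + 1, mx, periodic), j, k, mx, my)];
        const double sym = self[idx3(i, wrapc(j - 1, my, periodic), k, mx, my)];
        const double syp = self[idx3(i, wrapc(j + 1, my, periodic), k, mx, my)];
        const double szm = self[idx3(i, j, wrapc(k - 1, mz, periodic), mx, my)];
        const double szp = self[idx3(i, j, wrapc(k + 1, mz, periodic), mx, my)];

        // advecting velocity at this face: own comp = uc, others averaged
        double ua, va, wa;
        if (comp == 0) {
          ua = uc;
          // v at u-face (i, j+1/2 ...): average of 4 v faces
          int im = wrapc(i - 1, vx, periodic), ii = wrapc(i, vx, periodic);
          va = 0.25 * (v[idx3(im, j, k, vx, vy)] + v[idx3(ii, j, k, vx, vy)] +
                       v[idx3(im, wrapc(j + 1, vy, periodic), k, vx, vy)] +
                       v[idx3(ii, wrapc(j + 1, vy, periodic), k, vx, vy)]);
          int wzdim = nz + (periodic ? 0 : 1);
          wa = 0.25 * (w[idx3(im, j, k, wx_, wy_)] + w[idx3(ii, j, k, wx_, wy_)] +
                       w[idx3(im, j, wrapc(k + 1, wzdim, periodic), wx_, wy_)] +
                       w[idx3(ii, j, wrapc(k + 1, wzdim, periodic), wx_, wy_)]);
        } else if (comp == 1) {
          int jm = wrapc(j - 1, uy, periodic), jj = wrapc(j, uy, periodic);
          ua = 0.25 * (u[idx3(i, jm, k, ux, uy)] + u[idx3(i, jj, k, ux, uy)] +
                       u[idx3(wrapc(i + 1, ux, periodic), jm, k, ux, uy)] +
                       u[idx3(wrapc(i + 1, ux, periodic), jj, k, ux, uy)]);
          va = uc;
          int wzdim = nz + (periodic ? 0 : 1);
          wa = 0.25 * (w[idx3(i, jm, k, wx_, wy_)] + w[idx3(i, jj, k, wx_, wy_)] +
                       w[idx3(i, jm, wrapc(k + 1, wzdim, periodic), wx_, wy_)] +
                       w[idx3(i, jj, wrapc(k + 1, wzdim, periodic), wx_, wy_)]);
        } else {
          int km = wrapc(k - 1, nz, periodic), kk = wrapc(k, nz, periodic);
          ua = 0.25 * (u[idx3(i, j, km, ux, uy)] + u[idx3(i, j, kk, ux, uy)] +
                       u[idx3(wrapc(i + 1, ux, periodic), j, km, ux, uy)] +
                       u[idx3(wrapc(i + 1, ux, periodic), j, kk, ux, uy)]);
          int jp = wrapc(j + 1, vy, periodic);
          va = 0.25 * (v[idx3(i, j, km, vx, vy)] + v[idx3(i, jp, km, vx, vy)] +
                       v[idx3(i, j, kk, vx, vy)] + v[idx3(i, jp, kk, vx, vy)]);
          wa = uc;
        }

        double adv;
        if (upwind) {
          const double invh = 2.0 * inv2h;
          adv = (ua > 0 ? ua * (uc - sxm) : ua * (sxp - uc)) * invh +
                (va > 0 ? va * (uc - sym) : va * (syp - uc)) * invh +
                (wa > 0 ? wa * (uc - szm) : wa * (szp - uc)) * invh;
        } else {
          adv = ua * (sxp - sxm) * inv2h +
                va * (syp - sym) * inv2h +
                wa * (szp - szm) * inv2h;
        }
        const double lap = (sxp + sxm + syp + sym + szp + szm - 6.0 * uc) * invh2;
        out[id] = uc + dt * (-adv + nu * lap + f[id] / rho);
      }
}

// [[Rcpp::export]]
List cpp_advect_diffuse(NumericVector u, NumericVector v, NumericVector w,
                        NumericVector fx, NumericVector fy, NumericVector fz,
                        int nx, int ny, int nz, double h, double dt,
                        double rho, double mu, bool periodic,
                        bool upwind = false) {
  NumericVector un(clone(u)), vn(clone(v)), wn(clone(w));
  adv_diff_comp(REAL(u), REAL(v), REAL(w), REAL(fx), REAL(un), 0,
                nx, ny, nz, h, dt, rho, mu, periodic, upwind);
  adv_diff_comp(REAL(u), REAL(v), REAL(w), REAL(fy), REAL(vn), 1,
                nx, ny, nz, h, dt, rho, mu, periodic, upwind);
  adv_diff_comp(REAL(u), REAL(v), REAL(w), REAL(fz), REAL(wn), 2,
                nx, ny, nz, h, dt, rho, mu, periodic, upwind);
  return List::create(_["u"] = un, _["v"] = vn, _["w"] = wn);
}

// MAC divergence at cell centres
// [[Rcpp::export]]
NumericVector cpp_divergence(NumericVector u, NumericVector v, NumericVector w,
                             int nx, int ny, int nz, double h, bool periodic) {
  NumericVector d(Dimension(nx, ny, nz));
  const double *up = REAL(u), *vp = REAL(v), *wp = REAL(w);
  double *dp = REAL(d);
  const int ux = nx + (periodic ? 0 : 1);
  const int vy = ny + (periodic ? 0 : 1);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double due = up[idx3(periodic ? (i + 1) % nx : i + 1, j, k, ux, ny)] -
                     up[idx3(i, j, k, ux, ny)];
        double dvn = vp[idx3(i, periodic ? (j + 1) % ny : j + 1, k, nx, vy)] -
                     vp[idx3(i, j, k, nx, vy)];
        double dwt = wp[idx3(i, j, periodic ? (k + 1) % nz : k + 1, nx, ny)] -
                     wp[idx3(i, j, k, nx, ny)];
        dp[idx3(i, j, k, nx, ny)] = (due + dvn + dwt) / h;
      }
  return d;
}

// subtract (dt/rho) grad p from the staggered velocity; Dirichlet boundary
// pressures (lateral scalars pbc = (px0, px1, py0, py1) and end-face
// fields pz0, pz1, nx x ny) enter through ghost cells
// p_ghost = 2 p_b - p_interior.
// [[Rcpp::export]]
List cpp_grad_correct(NumericVector u, NumericVector v, NumericVector w,
                      NumericVector p, int nx, int ny, int nz, double h,
                      double dtorho, NumericVector pbc,
                      NumericMatrix pz0, NumericMatrix pz1, bool periodic) {
  NumericVector un(clone(u)), vn(clone(v)), wn(clone(w));
  const double *pp = REAL(p);
  const double c = dtorho / h;
  if (periodic) {
    double *up = REAL(un); double *vp = REAL(vn); double *wp = REAL(wn);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int im = (i - 1 + nx) % nx, jm = (j - 1 + ny) % ny, km = (k - 1 + nz) % nz;
          up[idx3(i, j, k, nx, ny)] -=
            c * (pp[idx3(i, j, k, nx, ny)] - pp[idx3(im, j, k, nx, ny)]);
          vp[idx3(i, j, k, nx, ny)] -=
            c * (pp[idx3(i, j, k, nx, ny)] - pp[idx3(i, jm, k, nx, ny)]);
          wp[idx3(i, j, k, nx, ny)] -=
            c * (pp[idx3(i, j, k, nx, ny)] - pp[idx3(i, j, km, nx, ny)]);
        }
    return List::create(_["u"] = un, _["v"] = vn, _["w"] = wn);
  }
  double *up = REAL(un);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i <= nx; ++i) {
        double pl = i == 0  ? 2.0 * pbc[0] - pp[idx3(0, j, k, nx, ny)]
                            : pp[idx3(i - 1, j, k, nx, ny)];
        double pr = i == nx ? 2.0 * pbc[1] - pp[idx3(nx - 1, j, k, nx, ny)]
                            : pp[idx3(i, j, k, nx, ny)];
        up[idx3(i, j, k, nx + 1, ny)] -= c * (pr - pl);
      }
  double *vp = REAL(vn);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j <= ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double pl = j == 0  ? 2.0 * pbc[2] - pp[idx3(i, 0, k, nx, ny)]
                            : pp[idx3(i, j - 1, k, nx, ny)];
        double pr = j == ny ? 2.0 * pbc[3] - pp[idx3(i, ny - 1, k, nx, ny)]
                            : pp[idx3(i, j, k, nx, ny)];
        vp[idx3(i, j, k, nx, ny + 1)] -= c * (pr - pl);
      }
  double *wp = REAL(wn);
  for (int k = 0; k <= nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double pl = k == 0  ? 2.0 * pz0(i, j) - pp[idx3(i, j, 0, nx, ny)]
                            : pp[idx3(i, j, k - 1, nx, ny)];
        double pr = k == nz ? 2.0 * pz1(i, j) - pp[idx3(i, j, nz - 1, nx, ny)]
                            : pp[idx3(i, j, k, nx, ny)];
        wp[idx3(i, j, k, nx, ny)] -= c * (pr - pl);
      }
  return List::create(_["u"] = un, _["v"] = vn, _["w"] = wn);
}

// ------------------------------------------------------- FE force assembly

// One-point-quadrature assembly of the weak-form elastic load vector on
// linear tetrahedra with the corrected PK1 stress.  Parameters per element
// (kPa): model 0 = polynomial (ca = c0, cb = c1), 1 = exponential
// (ca = c2, cb = c3); beta = volumetric penalty.  Element data arrive in
// cache-friendly transposed layouts: xt/xdt are 3 x nn (coordinates of a
// node contiguous), gradNt is 12 x ne (per-element shape gradients
// contiguous, index (a + 4*j) + 12*e), connt is 4 x ne.  Returns the
// nodal load vector (3 x nn, dyn), per-element deformation gradients and
// total energy (erg).
// [[Rcpp::export]]
List cpp_fe_forces(NumericMatrix xt, IntegerMatrix connt,
                   NumericVector gradNt,
                   NumericVector vol, IntegerVector model,
                   NumericVector ca, NumericVector cb, NumericVector beta,
                   Nullable<NumericMatrix> xdot = R_NilValue,
                   double eta = 0.0, double exp_cap = 1e308) {
  const int ne = connt.ncol(), nn = xt.ncol();
  NumericMatrix force(3, nn);
  NumericMatrix Fout(ne, 9);
  const double *gn0 = REAL(gradNt);
  const double *xp = REAL(xt);
  const int *cp = INTEGER(connt);
  double *fp = REAL(force);
  double energy = 0.0;
  const double KPA = 1e4;   // kPa -> dyn/cm^2
  const bool damped = eta > 0.0 && xdot.isNotNull();
  const double *xdp = nullptr;
  NumericMatrix xd;
  if (damped) { xd = NumericMatrix(xdot); xdp = REAL(xd); }
  for (int e = 0; e < ne; ++e) {
    const int *ce = cp + 4 * (R_xlen_t)e;
    const double *gn = gn0 + 12 * (R_xlen_t)e;
    int id[4];
    for (int a = 0; a < 4; ++a) id[a] = ce[a] - 1;
    double F[9], Fd[9] = {0,0,0,0,0,0,0,0,0};
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) {
        double s = 0.0;
        for (int a = 0; a < 4; ++a)
          s += xp[3 * (R_xlen_t)id[a] + i] * gn[a + 4 * j];
        F[i + 3 * j] = s;
        if (damped) {
          double sd = 0.0;
          for (int a = 0; a < 4; ++a)
            sd += xdp[3 * (R_xlen_t)id[a] + i] * gn[a + 4 * j];
          Fd[i + 3 * j] = sd;
        }
      }
    const double detF =
      F[0] * (F[4] * F[8] - F[7] * F[5]) -
      F[3] * (F[1] * F[8] - F[7] * F[2]) +
      F[6] * (F[1] * F[5] - F[4] * F[2]);
    if (detF <= 0.0)
      stop("inverted element %d (det F = %g)", e + 1, detF);
    double q = -3.0;
    for (int m = 0; m < 9; ++m) q += F[m] * F[m];
    // cofactor matrix / det = F^{-T}
    double G[9];
    G[0] = (F[4] * F[8] - F[7] * F[5]) / detF;
    G[1] = (F[6] * F[5] - F[3] * F[8]) / detF;
    G[2] = (F[3] * F[7] - F[6] * F[4]) / detF;
    G[3] = (F[7] * F[2] - F[1] * F[8]) / detF;
    G[4] = (F[0] * F[8] - F[6] * F[2]) / detF;
    G[5] = (F[6] * F[1] - F[0] * F[7]) / detF;
    G[6] = (F[1] * F[5] - F[4] * F[2]) / detF;
    G[7] = (F[3] * F[2] - F[0] * F[5]) / detF;
    G[8] = (F[0] * F[4] - F[3] * F[1]) / detF;
    double acoef, psi;
    if (model[e] == 0) {
      acoef = 2.0 * ca[e] + 4.0 * cb[e] * q;
      psi = ca[e] * q + cb[e] * q * q;
    } else {
      // exp_cap bounds the exponential stiffening argument; used by coarse
      // presets to keep spurious strain excursions from running away
      double arg = cb[e] * q * q;
      if (arg > exp_cap) arg = exp_cap;
      const double ex = std::exp(arg);
      acoef = 4.0 * ca[e] * cb[e] * q * ex;
      psi = ca[e] * (ex - 1.0);
    }
    const double logI3 = 2.0 * std::log(detF);
    psi += beta[e] / 4.0 * logI3 * logI3;
    energy += psi * vol[e] * KPA;
    const double bcoef = beta[e] * logI3 - acoef;
    double P[9];
    for (int m = 0; m < 9; ++m) P[m] = KPA * (acoef * F[m] + bcoef * G[m]);
    if (damped)
      for (int m = 0; m < 9; ++m) P[m] += KPA * eta * Fd[m];
    for (int m = 0; m < 9; ++m) Fout(e, m) = F[m];
    for (int a = 0; a < 4; ++a) {
      const double g0 = gn[a], g1 = gn[a + 4], g2 = gn[a + 8];
      double *fn = fp + 3 * (R_xlen_t)id[a];
      for (int i = 0; i < 3; ++i)
        fn[i] -= vol[e] * (P[i] * g0 + P[i + 3] * g1 + P[i + 6] * g2);
    }
  }
  return List::create(_["force"] = force, _["F"] = Fout,
                      _["energy"] = energy);
}
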