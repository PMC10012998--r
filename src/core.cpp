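#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Parameter vector layout; must match .parVector() on the R side.
enum ParIdx {
  P_u_o = 0, P_u_u, P_u_s, P_u_so, P_u_w_minus, P_u_w_plus, P_w_inf_star,
  P_theta_v, P_theta_v_minus, P_theta_w, P_theta_o,
  P_tau_v_plus, P_tau_v1_minus, P_tau_v2_minus,
  P_tau_w1_plus, P_tau_w2_plus, P_tau_w1_minus, P_tau_w2_minus, P_tau_w_inf,
  P_tau_fi, P_tau_si, P_tau_s1, P_tau_s2, P_tau_so1, P_tau_so2,
  P_tau_o1, P_tau_o2,
  P_k_w_plus, P_k_w_minus, P_k_s, P_k_so,
  P_D_par, P_D_perp,
  P_NPAR
};

// Heaviside with Theta(0) = 1 (right-continuous convention).
static inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }

// Right-hand side of the four-variable minimal ventricular model.
// tauScale multiplies the APD-regulating time constants
// (tau_w1+, tau_w2+, tau_so1, tau_so2, tau_si); scaling both sub-constants
// of an aggregate equals scaling the aggregate because the voltage
// dependence is affine in them.
static inline void cell_rhs(const double *p, double u, double v, double w,
                            double s, double tauScale, double &du, double &dv,
                            double &dw, double &ds) {
  const bool above_v  = u >= p[P_theta_v];        // Theta(0) = 1
  const bool above_vm = u >= p[P_theta_v_minus];
  const bool above_w  = u >= p[P_theta_w];
  const bool above_o  = u >= p[P_theta_o];

  double J_fi = 0.0, J_so, J_si = 0.0;
  if (above_v)
    J_fi = -(u - p[P_theta_v]) * (p[P_u_u] - u) * v / p[P_tau_fi];
  if (above_w) {
    const double tau_so = tauScale *
        (p[P_tau_so1] + (p[P_tau_so2] - p[P_tau_so1]) *
         (1.0 + std::tanh(p[P_k_so] * (u - p[P_u_so]))) / 2.0);
    J_so = 1.0 / tau_so;
    J_si = -w * s / (p[P_tau_si] * tauScale);
    const double tau_wp = tauScale *
        (p[P_tau_w1_plus] + (p[P_tau_w2_plus] - p[P_tau_w1_plus]) *
         (1.0 + std::tanh(p[P_k_w_plus] * (u - p[P_u_w_plus]))) / 2.0);
    dw = -w / tau_wp;
  } else {
    const double tau_o = above_o ? p[P_tau_o2] : p[P_tau_o1];
    J_so = (u - p[P_u_o]) / tau_o;
    const double tau_wm = p[P_tau_w1_minus] +
        (p[P_tau_w2_minus] - p[P_tau_w1_minus]) *
        (1.0 + std::tanh(p[P_k_w_minus] * (u - p[P_u_w_minus]))) / 2.0;
    const double w_inf = above_o ? p[P_w_inf_star]
                                 : 1.0 - u / p[P_tau_w_inf];
    dw = (w_inf - w) / tau_wm;
  }
  du = -(J_fi + J_so + J_si);
  if (above_v) dv = -v / p[P_tau_v_plus];
  else {
    const double v_inf = above_vm ? 0.0 : 1.0;
    const double tau_vm = above_vm ? p[P_tau_v2_minus] : p[P_tau_v1_minus];
    dv = (v_inf - v) / tau_vm;
  }
  const double tau_s = above_w ? p[P_tau_s2] : p[P_tau_s1];
  ds = ((1.0 + std::tanh(p[P_k_s] * (u - p[P_u_s]))) / 2.0 - s) / tau_s;
}

// Tabulated sigmoids for the tissue solver: the four tanh-shaped terms of
// the model on a uniform grid over u in [-2, 3] with spacing 2^-10, linear
// interpolation.  Grid nodes are exact (u = 0 is a node, so the resting
// fixed point is preserved to machine precision); interpolation error is
// below 4e-5 on the steepest sigmoid, far below the Euler discretization
// error.  The 0D integrator keeps the closed-form expressions.
struct RateTables {
  static const int N = 5121;
  double u0, h, inv_h;
  std::vector<double> sig_wp, sig_wm, sig_so, s_inf;
  explicit RateTables(const double *p)
      : u0(-2.0), h(1.0 / 1024.0), inv_h(1024.0), sig_wp(N), sig_wm(N),
        sig_so(N), s_inf(N) {
    for (int i = 0; i < N; ++i) {
      const double u = u0 + i * h;
      sig_wp[i] = (1.0 + std::tanh(p[P_k_w_plus] * (u - p[P_u_w_plus]))) / 2.0;
      sig_wm[i] = (1.0 + std::tanh(p[P_k_w_minus] * (u - p[P_u_w_minus]))) / 2.0;
      sig_so[i] = (1.0 + std::tanh(p[P_k_so] * (u - p[P_u_so]))) / 2.0;
      s_inf[i]  = (1.0 + std::tanh(p[P_k_s] * (u - p[P_u_s]))) / 2.0;
    }
  }
  inline void lookup(double u, double &wp, double &wm, double &so,
                     double &si) const {
    double x = (u - u0) * inv_h;
    if (x < 0.0) x = 0.0;
    if (x > N - 1.001) x = N - 1.001;
    const int i = (int)x;
    const double f = x - i;
    wp = sig_wp[i] + f * (sig_wp[i + 1] - sig_wp[i]);
    wm = sig_wm[i] + f * (sig_wm[i + 1] - sig_wm[i]);
    so = sig_so[i] + f * (sig_so[i + 1] - sig_so[i]);
    si = s_inf[i] + f * (s_inf[i + 1] - s_inf[i]);
  }
};

// cell_rhs with tabulated sigmoids (tissue fast path)
static inline void cell_rhs_lut(const double *p, const RateTables &tab,
                                double u, double v, double w, double s,
                                double tauScale, double &du, double &dv,
                                double &dw, double &ds) {
  const bool above_v  = u >= p[P_theta_v];
  const bool above_vm = u >= p[P_theta_v_minus];
  const bool above_w  = u >= p[P_theta_w];
  const bool above_o  = u >= p[P_theta_o];
  double g_wp, g_wm, g_so, g_si;
  tab.lookup(u, g_wp, g_wm, g_so, g_si);

  double J_fi = 0.0, J_so, J_si = 0.0;
  if (above_w) {
    const double tau_so = tauScale *
        (p[P_tau_so1] + (p[P_tau_so2] - p[P_tau_so1]) * g_so);
    J_so = 1.0 / tau_so;
    J_si = -w * s / (p[P_tau_si] * tauScale);
    const double tau_wp = tauScale *
        (p[P_tau_w1_plus] + (p[P_tau_w2_plus] - p[P_tau_w1_plus]) * g_wp);
    dw = -w / tau_wp;
  } else {
    const double tau_o = above_o ? p[P_tau_o2] : p[P_tau_o1];
    J_so = (u - p[P_u_o]) / tau_o;
    const double tau_wm = p[P_tau_w1_minus] +
        (p[P_tau_w2_minus] - p[P_tau_w1_minus]) * g_wm;
    const double w_inf = above_o ? p[P_w_inf_star]
                                 : 1.0 - u / p[P_tau_w_inf];
    dw = (w_inf - w) / tau_wm;
  }
  if (above_v)
    J_fi = -(u - p[P_theta_v]) * (p[P_u_u] - u) * v / p[P_tau_fi];
  du = -(J_fi + J_so + J_si);
  if (above_v) dv = -v / p[P_tau_v_plus];
  else {
    const double tau_vm = above_vm ? p[P_tau_v2_minus] : p[P_tau_v1_minus];
    dv = ((above_vm ? 0.0 : 1.0) - v) / tau_vm;
  }
  const double tau_s = above_w ? p[P_tau_s2] : p[P_tau_s1];
  ds = (g_si - s) / tau_s;
}

// [[Rcpp::export]]
NumericVector cpp_cell_rhs(NumericVector state, NumericVector pars,
                           double tauScale = 1.0) {
  double du, dv, dw, ds;
  cell_rhs(REAL(pars), state[0], state[1], state[2], state[3], tauScale,
           du, dv, dw, ds);
  return NumericVector::create(du, dv, dw, ds);
}

// Integrate the 0D cell model with explicit Euler under a train of
// rectangular stimulus pulses.  Records the state every `recordEvery`
// steps (the first record is after `recordEvery` steps).
// [[Rcpp::export]]
List cpp_integrate_cell(NumericVector state, NumericVector pars, double dt,
                        int nSteps, NumericVector stimTimes, double stimDur,
                        double stimAmp, int recordEvery, double tauScale = 1.0) {
  const double *p = REAL(pars);
  double u = state[0], v = state[1], w = state[2], s = state[3];
  const int nRec = nSteps / recordEvery;
  NumericVector tu(nRec), ru(nRec), rv(nRec), rw(nRec), rs(nRec);
  int iRec = 0;
  int kStim = 0;
  const int nStim = stimTimes.size();
  double du, dv, dw, ds;
  for (int step = 0; step < nSteps; ++step) {
    const double t = step * dt;
    while (kStim < nStim && t >= stimTimes[kStim] + stimDur) ++kStim;
    const double Is =
        (kStim < nStim && t >= stimTimes[kStim] && t < stimTimes[kStim] + stimDur)
            ? stimAmp : 0.0;
    cell_rhs(p, u, v, w, s, tauScale, du, dv, dw, ds);
    u += dt * (du + Is);
    v += dt * dv;
    w += dt * dw;
    s += dt * ds;
    if ((step + 1) % recordEvery == 0 && iRec < nRec) {
      tu[iRec] = (step + 1) * dt;
      ru[iRec] = u; rv[iRec] = v; rw[iRec] = w; rs[iRec] = s;
      ++iRec;
    }
  }
  return List::create(_["time"] = tu, _["u"] = ru, _["v"] = rv, _["w"] = rw,
                      _["s"] = rs,
                      _["final"] = NumericVector::create(u, v, w, s));
}

static inline double harm(double a, double b) {
  const double s = a + b;
  return s > 0.0 ? 2.0 * a * b / s : 0.0;
}

// Divergence-form anisotropic Laplacian (1/phi) div(phi D grad u) with
// zero-flux outer boundaries.  All terms are assembled as face fluxes so
// that the phi-weighted total of u is conserved exactly under pure
// diffusion.  D11/D22 are averaged harmonically on faces, D12
// arithmetically; phi arithmetically, with a floor on the dividing phi.
static void laplacian_core(const double *u, const double *D11,
                           const double *D12, const double *D22,
                           const double *phi, int nx, int ny, double dx,
                           double phiMin, double *out,
                           std::vector<double> &dudxC,
                           std::vector<double> &dudyC) {
  const double inv_dx = 1.0 / dx;
  // centered first derivatives (one-sided at the outer boundary)
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const int k = i + nx * j;
      const int im = i > 0 ? k - 1 : k;
      const int ip = i < nx - 1 ? k + 1 : k;
      const int jm = j > 0 ? k - nx : k;
      const int jp = j < ny - 1 ? k + nx : k;
      const double hx = (i > 0 && i < nx - 1) ? 2.0 * dx : dx;
      const double hy = (j > 0 && j < ny - 1) ? 2.0 * dx : dx;
      dudxC[k] = (u[ip] - u[im]) / hx;
      dudyC[k] = (u[jp] - u[jm]) / hy;
    }
  }
  // x-face fluxes Fx(i+1/2, j), i = 0..nx-2; y-face fluxes analogous
  std::vector<double> Fx((size_t)(nx - 1) * ny), Fy((size_t)nx * (ny - 1));
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx - 1; ++i) {
      const int k = i + nx * j;
      const double phif = 0.5 * (phi[k] + phi[k + 1]);
      const double d11 = harm(D11[k], D11[k + 1]);
      const double d12 = 0.5 * (D12[k] + D12[k + 1]);
      const double dudx = (u[k + 1] - u[k]) * inv_dx;
      const double dudy = 0.5 * (dudyC[k] + dudyC[k + 1]);
      Fx[i + (size_t)(nx - 1) * j] = phif * (d11 * dudx + d12 * dudy);
    }
  }
  for (int j = 0; j < ny - 1; ++j) {
    for (int i = 0; i < nx; ++i) {
      const int k = i + nx * j;
      const double phif = 0.5 * (phi[k] + phi[k + nx]);
      const double d22 = harm(D22[k], D22[k + nx]);
      const double d12 = 0.5 * (D12[k] + D12[k + nx]);
      const double dudy = (u[k + nx] - u[k]) * inv_dx;
      const double dudx = 0.5 * (dudxC[k] + dudxC[k + nx]);
      Fy[i + (size_t)nx * j] = phif * (d12 * dudx + d22 * dudy);
    }
  }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const int k = i + nx * j;
      const double fxp = i < nx - 1 ? Fx[i + (size_t)(nx - 1) * j] : 0.0;
      const double fxm = i > 0 ? Fx[i - 1 + (size_t)(nx - 1) * j] : 0.0;
      const double fyp = j < ny - 1 ? Fy[i + (size_t)nx * j] : 0.0;
      const double fym = j > 0 ? Fy[i + (size_t)nx * (j - 1)] : 0.0;
      const double ph = phi[k] > phiMin ? phi[k] : phiMin;
      out[k] = (fxp - fxm + fyp - fym) * inv_dx / ph;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_laplacian(NumericMatrix u, NumericMatrix D11,
                            NumericMatrix D12, NumericMatrix D22,
                            NumericMatrix phi, double dx,
                            double phiMin = 1e-3) {
  const int nx = u.nrow(), ny = u.ncol();
  NumericMatrix out(nx, ny);
  std::vector<double> dx1((size_t)nx * ny), dy1((size_t)nx * ny);
  laplacian_core(REAL(u), REAL(D11), REAL(D12), REAL(D22), REAL(phi), nx, ny,
                 dx, phiMin, REAL(out), dx1, dy1);
  return out;
}

// Explicit-Euler monodomain integration on a 2D grid.
// Pixels with phi < phiCut are frozen (outside the phase-field support).
// Face coefficients of the divergence-form operator are constant in time
// and precomputed once; the cross-term (D12) path is skipped entirely for
// axis-aligned fibers.
// [[Rcpp::export]]
List cpp_simulate_tissue(NumericMatrix u0, NumericMatrix v0, NumericMatrix w0,
                         NumericMatrix s0, NumericVector pars,
                         NumericMatrix D11, NumericMatrix D12,
                         NumericMatrix D22, NumericMatrix tauScale,
                         NumericMatrix phi, double dx, double dt, int nSteps,
                         NumericMatrix stimMask, NumericVector stimTimes,
                         double stimDur, double stimAmp, int recordEvery,
                         bool includeCurrents = true, double phiMin = 1e-3,
                         double phiCut = 1e-3) {
  const int nx = u0.nrow(), ny = u0.ncol();
  const size_t n = (size_t)nx * ny;
  const double *p = REAL(pars);
  std::vector<double> u(REAL(u0), REAL(u0) + n), v(REAL(v0), REAL(v0) + n),
      w(REAL(w0), REAL(w0) + n), s(REAL(s0), REAL(s0) + n), uNew(u);
  const double *ts = REAL(tauScale), *ph = REAL(phi), *sm = REAL(stimMask);
  const double *pD12 = REAL(D12);
  const int nRec = recordEvery > 0 ? nSteps / recordEvery : 0;
  NumericVector stack(Dimension(nx, ny, std::max(nRec, 1)));
  NumericVector recTimes(std::max(nRec, 1));
  double *st = REAL(stack);
  int iRec = 0, kStim = 0;
  const int nStim = stimTimes.size();
  double du, dv, dw, ds;

  const RateTables tab(p);
  bool hasCross = false;
  for (size_t k = 0; k < n; ++k)
    if (pD12[k] != 0.0) { hasCross = true; break; }
  const double inv_dx = 1.0 / dx, inv_dx2 = inv_dx * inv_dx;
  // x-face (i+1/2, j) and y-face (i, j+1/2) coefficients
  const size_t nfx = (size_t)(nx - 1) * ny, nfy = (size_t)nx * (ny - 1);
  std::vector<double> ax(nfx), bx(hasCross ? nfx : 0);
  std::vector<double> ay(nfy), by(hasCross ? nfy : 0);
  {
    const double *d11 = REAL(D11), *d22 = REAL(D22);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        const size_t k = i + (size_t)nx * j, f = i + (size_t)(nx - 1) * j;
        const double phif = 0.5 * (ph[k] + ph[k + 1]);
        ax[f] = phif * harm(d11[k], d11[k + 1]) * inv_dx2;
        if (hasCross)
          bx[f] = phif * 0.5 * (pD12[k] + pD12[k + 1]);
      }
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t k = i + (size_t)nx * j, f = i + (size_t)nx * j;
        const double phif = 0.5 * (ph[k] + ph[k + nx]);
        ay[f] = phif * harm(d22[k], d22[k + nx]) * inv_dx2;
        if (hasCross)
          by[f] = phif * 0.5 * (pD12[k] + pD12[k + nx]);
      }
  }
  std::vector<double> invphi(n), dxC(hasCross ? n : 0), dyC(hasCross ? n : 0);
  for (size_t k = 0; k < n; ++k)
    invphi[k] = 1.0 / (ph[k] > phiMin ? ph[k] : phiMin);

  for (int step = 0; step < nSteps; ++step) {
    const double t = step * dt;
    while (kStim < nStim && t >= stimTimes[kStim] + stimDur) ++kStim;
    const bool stimOn = kStim < nStim && t >= stimTimes[kStim] &&
                        t < stimTimes[kStim] + stimDur;
    if (hasCross) {
      // centered first derivatives (one-sided at the outer boundary)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const size_t k = i + (size_t)nx * j;
          const size_t im = i > 0 ? k - 1 : k, ip = i < nx - 1 ? k + 1 : k;
          const size_t jm = j > 0 ? k - nx : k, jp = j < ny - 1 ? k + nx : k;
          const double hx = (i > 0 && i < nx - 1) ? 2.0 * dx : dx;
          const double hy = (j > 0 && j < ny - 1) ? 2.0 * dx : dx;
          dxC[k] = (u[ip] - u[im]) / hx;
          dyC[k] = (u[jp] - u[jm]) / hy;
        }
    }
    for (int j = 0; j < ny; ++j) {
      const bool jlo = j > 0, jhi = j < ny - 1;
      for (int i = 0; i < nx; ++i) {
        const size_t k = i + (size_t)nx * j;
        if (ph[k] < phiCut) continue;
        const size_t fxp = i + (size_t)(nx - 1) * j;
        const size_t fyp = i + (size_t)nx * j, fym = fyp - nx;
        double flux = 0.0;
        if (i < nx - 1) flux += ax[fxp] * (u[k + 1] - u[k]);
        if (i > 0) flux -= ax[fxp - 1] * (u[k] - u[k - 1]);
        if (jhi) flux += ay[fyp] * (u[k + nx] - u[k]);
        if (jlo) flux -= ay[fym] * (u[k] - u[k - nx]);
        if (hasCross) {
          double cr = 0.0;
          if (i < nx - 1) cr += bx[fxp] * 0.5 * (dyC[k] + dyC[k + 1]);
          if (i > 0) cr -= bx[fxp - 1] * 0.5 * (dyC[k - 1] + dyC[k]);
          if (jhi) cr += by[fyp] * 0.5 * (dxC[k] + dxC[k + nx]);
          if (jlo) cr -= by[fym] * 0.5 * (dxC[k - nx] + dxC[k]);
          flux += cr * inv_dx;
        }
        double rhs = flux * invphi[k];
        if (includeCurrents) {
          cell_rhs_lut(p, tab, u[k], v[k], w[k], s[k], ts[k], du, dv, dw, ds);
          rhs += du;
          v[k] += dt * dv;
          w[k] += dt * dw;
          s[k] += dt * ds;
        }
        if (stimOn && sm[k] > 0.5) rhs += stimAmp;
        uNew[k] = u[k] + dt * rhs;
      }
    }
    std::swap(u, uNew);
    if (recordEvery > 0 && (step + 1) % recordEvery == 0 && iRec < nRec) {
      std::copy(u.begin(), u.end(), st + n * (size_t)iRec);
      recTimes[iRec] = (step + 1) * dt;
      ++iRec;
    }
  }
  NumericMatrix uf(nx, ny), vf(nx, ny), wf(nx, ny), sf(nx, ny);
  std::copy(u.begin(), u.end(), REAL(uf));
  std::copy(v.begin(), v.end(), REAL(vf));
  std::copy(w.begin(), w.end(), REAL(wf));
  std::copy(s.begin(), s.end(), REAL(sf));
  return List::create(_["stack"] = stack, _["times"] = recTimes,
                      _["u"] = uf, _["v"] = vf, _["w"] = wf, _["s"] = sf);
}

// Mask-aware normalized convolution with a Gaussian kernel truncated at a
// (Euclidean) pixel radius.  Pixels outside the mask are left untouched and
// contribute no weight.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix x, double sigma, int radius,
                                LogicalMatrix mask) {
  const int nx = x.nrow(), ny = x.ncol();
  NumericMatrix out(nx, ny);
  const int r = radius;
  std::vector<double> kern((2 * r + 1) * (2 * r + 1), 0.0);
  for (int dj = -r; dj <= r; ++dj)
    for (int di = -r; di <= r; ++di)
      if (di * di + dj * dj <= r * r)
        kern[(di + r) + (2 * r + 1) * (dj + r)] =
            std::exp(-0.5 * (di * di + dj * dj) / (sigma * sigma));
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j)) { out(i, j) = x(i, j); continue; }
      double acc = 0.0, wsum = 0.0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -r; di <= r; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nx || !mask(ii, jj)) continue;
          const double wk = kern[(di + r) + (2 * r + 1) * (dj + r)];
          acc += wk * x(ii, jj);
          wsum += wk;
        }
      }
      out(i, j) = wsum > 0.0 ? acc / wsum : x(i, j);
    }
  }
  return out;
}

// Per-trace APD extraction by threshold crossing with linear interpolation.
// traces: nt x npix (one column per pixel/trace).  Baseline is the given
// per-trace quantile; threshold = baseline + thrFrac * (max - baseline).
// [[Rcpp::export]]
List cpp_apd_traces(NumericMatrix traces, double dtFrame, double thrFrac,
                    double baselineQ, int maxBeats) {
  const int nt = traces.nrow(), np = traces.ncol();
  NumericMatrix apds(maxBeats, np), tups(maxBeats, np);
  std::fill(apds.begin(), apds.end(), NA_REAL);
  std::fill(tups.begin(), tups.end(), NA_REAL);
  IntegerVector nb(np);
  NumericVector amps(np);
  std::vector<double> buf(nt);
  for (int pIdx = 0; pIdx < np; ++pIdx) {
    const double *x = &traces(0, pIdx);
    std::copy(x, x + nt, buf.begin());
    std::sort(buf.begin(), buf.end());
    const double hIdx = baselineQ * (nt - 1);
    const int lo = (int)std::floor(hIdx);
    const double base = buf[lo] + (hIdx - lo) * (buf[std::min(lo + 1, nt - 1)] - buf[lo]);
    const double mx = buf[nt - 1];
    const double amp = mx - base;
    amps[pIdx] = amp;
    if (amp <= 0.0) continue;
    const double thr = base + thrFrac * amp;
    int count = 0;
    bool inBeat = x[0] >= thr;  // partial beat at start is discarded
    bool firstPartial = inBeat;
    double tUp = 0.0;
    for (int k = 1; k < nt; ++k) {
      if (!inBeat && x[k - 1] < thr && x[k] >= thr) {
        tUp = (k - 1 + (thr - x[k - 1]) / (x[k] - x[k - 1])) * dtFrame;
        inBeat = true;
        firstPartial = false;
      } else if (inBeat && x[k - 1] >= thr && x[k] < thr) {
        const double tDown =
            (k - 1 + (x[k - 1] - thr) / (x[k - 1] - x[k])) * dtFrame;
        if (!firstPartial && count < maxBeats) {
          apds(count, pIdx) = tDown - tUp;
          tups(count, pIdx) = tUp;
          ++count;
        }
        inBeat = false;
        firstPartial = false;
      }
    }
    nb[pIdx] = count;
  }
  return List::create(_["apd"] = apds, _["t_up"] = tups, _["n_beats"] = nb,
                      _["amplitude"] = amps);
}

// 4-connected component labelling of a binary image.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
        for (int d = 0; d < 4; ++d) {
          const int ni = ci + di[d], nj = cj + dj[d];
          if (ni < 0 || ni >= nx || nj < 0 || nj >= ny) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}
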