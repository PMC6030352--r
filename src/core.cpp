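// Compiled core: closed-loop circulation + three-segment heart RHS and an
// adaptive embedded RK45 (Cash-Karp) integrator. Mirrors the pure-R
// reference path (system_derivatives / solve_heart); the test suite asserts
// agreement between the two.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---- packed parameter layout (keep in step with pack_params() in R) ----
enum {
  iHR = 0, iC_Ao, iC_SV, iC_PA, iC_PV, iPVR, iSVR,
  iR_av, iR_pval, iR_mv, iR_tv, iR_ven_s, iR_ven_p,
  iV0_Ao, iV0_SV, iV0_PA, iV0_PV,
  iCA_max, iCA_min, iT_onset, iD_a,
  iACT,
  iWALL0                       // = 22, start of per-wall blocks
};
static const int WBLK = 25;    // Vw, Am_ref + 23 sarcomere parameters
// sarcomere offsets within a wall block, after Vw (0) and Am_ref (1)
enum { sLs_ref = 0, sLs_slack, sK2, sX0, sF, sG, sCa_dia, sCa_amp, sTau,
       sCa50, sHill, sKt, sAt, sKc, sAc, sLc, sConC, sMu, sLSE, sVmax, sOW,
       sKcomp, sAcomp };
static const int NPAR = 22 + 3 * WBLK;   // 97
static const int NSTATE = 17;            // 8 volumes + 3 x (Ls, A, xbar)
static const int NOUT = 18;
static const double KPA2MMHG = 7.50062;

// [[Rcpp::export]]
int c_param_count() { return NPAR; }

// positive modulo via floor (also handles negative x)
static inline double mod_pos(double x, double y) {
  double r = x - std::floor(x / y) * y;
  if (r >= y) r -= y;
  if (r < 0) r = 0;
  return r;
}

// ---- cap geometry ----
static double cap_x_from_Vm(double Vm, double y) {
  double x = Vm / ((M_PI / 2.0) * y * y);
  for (int i = 0; i < 100; ++i) {
    double f = (M_PI / 6.0) * x * (x * x + 3 * y * y) - Vm;
    double fp = (M_PI / 6.0) * (3 * x * x + 3 * y * y);
    double dx = f / fp;
    x -= dx;
    if (std::fabs(dx) < 1e-15 * std::max(1.0, std::fabs(x))) return x;
  }
  // bisection fallback (f strictly increasing in x)
  double lo = -1, hi = 1;
  while ((M_PI / 6.0) * lo * (lo * lo + 3 * y * y) > Vm) lo *= 2;
  while ((M_PI / 6.0) * hi * (hi * hi + 3 * y * y) < Vm) hi *= 2;
  for (int i = 0; i < 200; ++i) {
    double mid = 0.5 * (lo + hi);
    if ((M_PI / 6.0) * mid * (mid * mid + 3 * y * y) < Vm) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// ---- sarcomere mechanics ----
static inline double overlap_f(double Ls, const double* sp) {
  double o = 1.0 - std::fabs(Ls - sp[sLs_ref]) / sp[sOW];
  return o > 0 ? o : 0.0;
}
static inline double passive_f(double Ls, const double* sp) {
  double t = (Ls > sp[sLs_slack])
    ? sp[sKt] * (std::exp(sp[sAt] * (Ls - sp[sLs_slack])) - 1.0) : 0.0;
  double c = (Ls > sp[sLc])
    ? sp[sConC] * sp[sKc] * (std::exp(sp[sAc] * (Ls - sp[sLc])) - 1.0) : 0.0;
  // compressive support below slack: the wall resists collapse
  double q = (Ls < sp[sLs_slack])
    ? -sp[sKcomp] * (std::exp(sp[sAcomp] * (sp[sLs_slack] - Ls)) - 1.0) : 0.0;
  return t + c + q;
}
static inline void fiber_stress_c(const double* sp, double Ls, double A,
                                  double xb, double eps, double act,
                                  double* sigma, double* dLs) {
  double Ltot = sp[sLs_ref] * std::exp(eps);
  double eSE = Ltot - Ls;
  double vraw = sp[sVmax] * (eSE / sp[sLSE] - 1.0);
  // smooth saturation: |dLs/dt| approaches a few times the unloaded-velocity
  // scale (bounds extreme startup transients, near-linear in normal range)
  double vcap = 6.0 * sp[sVmax];
  double v = vcap * std::tanh(vraw / vcap);
  double sact = act * sp[sK2] * overlap_f(Ls, sp) * A * xb;
  *sigma = sact + passive_f(Ls, sp) + sp[sMu] * v;
  *dLs = v;
}

// ---- junction force balance ----
struct GeoOut {
  double x[3], Am[3], Cm[3], Tm[3], eps[3], sigma[3], dLs[3];
  double VmS, y, PLV, PRV, resid;
};

// residual of (sum Tx, sum Ty); wall states ws = (Ls,A,xb) x (L,S,R)
static int junction_resid(double VmS, double y, double VLV, double VRV,
                          const double* P, const double* ws, double act,
                          double* RTx, double* RTy, double* Tsc, GeoOut* go) {
  const double* b[3] = { P + iWALL0, P + iWALL0 + WBLK, P + iWALL0 + 2 * WBLK };
  double VwL = b[0][0], VwS = b[1][0], VwR = b[2][0];
  // the junction ring must be commensurate with the heart size: this
  // excludes the spurious pinch-off (y -> 0) and inflation (y -> inf)
  // attractors of the raw force balance
  double r_est = std::cbrt(3.0 * (VLV + VRV + VwL + VwS + VwR) / (4.0 * M_PI));
  if (!std::isfinite(y) || !std::isfinite(VmS) || y < 0.2 * r_est ||
      y > 3.0 * r_est || std::fabs(VmS) > 1e4) return 1;
  double Vm[3];
  Vm[0] = -VLV - 0.5 * VwL - 0.5 * VwS + VmS;
  Vm[1] = VmS;
  Vm[2] =  VRV + 0.5 * VwR + 0.5 * VwS + VmS;
  double Tx = 0, Ty = 0, Ts = 0;
  for (int w = 0; w < 3; ++w) {
    double x = cap_x_from_Vm(Vm[w], y);
    double d = x * x + y * y;
    double Am = M_PI * d;
    double Cm = 2 * x / d;
    double eps = 0.5 * std::log(Am / b[w][1]);
    if (std::fabs(eps) > 1.5) return 1;  // |strain| beyond physical range
    const double* sp = b[w] + 2;
    double A = std::min(std::max(ws[3 * w + 1], 0.0), 1.0);
    double sigma, dLs;
    fiber_stress_c(sp, ws[3 * w], A, ws[3 * w + 2], eps, act, &sigma, &dLs);
    double Tm = sigma * b[w][0] / (2 * Am);
    Tx += Tm * (2 * x * y / d);
    Ty += Tm * ((y * y - x * x) / d);
    Ts += std::fabs(Tm);
    if (go) {
      go->x[w] = x; go->Am[w] = Am; go->Cm[w] = Cm; go->Tm[w] = Tm;
      go->eps[w] = eps; go->sigma[w] = sigma; go->dLs[w] = dLs;
    }
  }
  if (!std::isfinite(Tx) || !std::isfinite(Ty)) return 1;
  *RTx = Tx; *RTy = Ty;
  if (Tsc) *Tsc = Ts;
  return 0;
}

// coarse scan for the basin of the physical root (cold starts and rescue)
static void junction_grid_start(double VLV, double VRV, const double* P,
                                const double* ws, double act,
                                double* u0, double* u1) {
  const double* b0 = P + iWALL0;
  double VwL = b0[0], VwR = b0[2 * WBLK];
  double Vtot = VLV + VRV + VwL + b0[WBLK] + VwR;
  double r_est = std::cbrt(3.0 * Vtot / (4.0 * M_PI));
  double best = HUGE_VAL;
  *u0 = 0.15 * VLV; *u1 = 0.9 * r_est;
  for (int iv = 0; iv < 25; ++iv) {
    double v = -(VLV + VwL) + (VRV + VwR + VLV + VwL) * iv / 24.0;
    for (int iy = 0; iy < 15; ++iy) {
      double yy = r_est * (0.4 + 1.6 * iy / 14.0);
      double q0, q1, qs;
      GeoOut gg;
      if (junction_resid(v, yy, VLV, VRV, P, ws, act, &q0, &q1, &qs, &gg))
        continue;
      // only physiological configurations: contorted roots (septum folded
      // deep into a ventricle) live at extreme strains
      double me = std::max(std::fabs(gg.eps[0]),
                           std::max(std::fabs(gg.eps[1]), std::fabs(gg.eps[2])));
      if (me > 0.6) continue;
      double sc = std::sqrt(q0 * q0 + q1 * q1) / (qs + 1e-30);
      if (sc < best) { best = sc; *u0 = v; *u1 = yy; }
    }
  }
}

// Newton on the tension-scaled residual (scale invariance removes the
// false minimum at infinite junction radius, where all tensions vanish).
// Returns 0 on success.
static int solve_junction_from(double u0, double u1, double VLV, double VRV,
                               const double* P, const double* ws, double act,
                               double* warm, GeoOut* go, double tol) {
  double r0, r1, Ts;
  if (junction_resid(u0, u1, VLV, VRV, P, ws, act, &r0, &r1, &Ts, NULL))
    return 1;
  const double TINY = 1e-30;
  double nr = std::sqrt(r0 * r0 + r1 * r1) / (Ts + TINY);
  for (int it = 0; it < 80; ++it) {
    if (nr < tol) break;
    double h0 = 1e-6 * std::max(1.0, std::fabs(u0));
    double h1 = 1e-6 * std::max(1.0, std::fabs(u1));
    double a0, a1, c0, c1, tdum;
    if (junction_resid(u0 + h0, u1, VLV, VRV, P, ws, act, &a0, &a1, &tdum, NULL)) {
      h0 = -h0;  // backward difference near a domain edge
      if (junction_resid(u0 + h0, u1, VLV, VRV, P, ws, act, &a0, &a1, &tdum, NULL))
        return 1;
    }
    if (junction_resid(u0, u1 + h1, VLV, VRV, P, ws, act, &c0, &c1, &tdum, NULL)) {
      h1 = -h1;
      if (junction_resid(u0, u1 + h1, VLV, VRV, P, ws, act, &c0, &c1, &tdum, NULL))
        return 1;
    }
    double J00 = (a0 - r0) / h0, J10 = (a1 - r1) / h0;
    double J01 = (c0 - r0) / h1, J11 = (c1 - r1) / h1;
    double det = J00 * J11 - J01 * J10;
    if (std::fabs(det) < 1e-300) return 1;
    double d0 = (-r0 * J11 + r1 * J01) / det;
    double d1 = (-r1 * J00 + r0 * J10) / det;
    // trust region: cap the relative step so iterates stay local
    double dn = std::sqrt(d0 * d0 + d1 * d1);
    double un = 1.0 + std::sqrt(u0 * u0 + u1 * u1);
    if (dn > un) { d0 *= un / dn; d1 *= un / dn; }
    double lam = 1.0; bool ok = false;
    for (int bt = 0; bt < 40; ++bt) {
      double t0 = u0 + lam * d0, t1 = u1 + lam * d1;
      double q0, q1, qs;
      if (t1 > 1e-6 &&
          !junction_resid(t0, t1, VLV, VRV, P, ws, act, &q0, &q1, &qs, NULL)) {
        double nq = std::sqrt(q0 * q0 + q1 * q1) / (qs + TINY);
        if (nq < nr) {
          u0 = t0; u1 = t1; r0 = q0; r1 = q1; Ts = qs; nr = nq; ok = true;
          break;
        }
      }
      lam *= 0.5;
    }
    if (!ok) {
      if (nr < 1e-8) break;  // stagnated at the FD noise floor; acceptable
      return 1;
    }
    if (it == 79 && nr >= 1e-8) return 1;
  }
  if (junction_resid(u0, u1, VLV, VRV, P, ws, act, &r0, &r1, &Ts, go)) return 1;
  warm[0] = u0; warm[1] = u1;
  if (go) {
    go->VmS = u0; go->y = u1;
    go->PLV = 2 * std::fabs(go->Tm[0] * go->Cm[0]) * KPA2MMHG;
    go->PRV = 2 * std::fabs(go->Tm[2] * go->Cm[2]) * KPA2MMHG;
    go->resid = std::sqrt(r0 * r0 + r1 * r1);
  }
  return 0;
}

// Damped Gauss-Newton (Levenberg) minimizer of the tension-scaled
// imbalance, used when the exact equilibrium transiently ceases to exist
// (saddle-node of the junction system): the geometry then tracks the
// least-imbalance configuration, which continues the physical branch
// smoothly through the fold. Returns 0 unless the landscape is invalid.
static int track_junction_lsq(double VLV, double VRV, const double* P,
                              const double* ws, double act, double* warm,
                              GeoOut* go) {
  const double* b0 = P + iWALL0;
  double Vtot = VLV + VRV + b0[0] + b0[WBLK] + b0[2 * WBLK];
  double r_est = std::cbrt(3.0 * Vtot / (4.0 * M_PI));
  double u0 = warm[0];
  double u1 = std::max(warm[1], 0.32 * r_est);  // stay off the pinch edge
  double r0, r1, Ts;
  if (junction_resid(u0, u1, VLV, VRV, P, ws, act, &r0, &r1, &Ts, NULL))
    return 1;
  // continuation: bound the per-call displacement (the tracker follows the
  // fold incrementally across successive derivative evaluations)
  double U0 = u0, U1 = u1;
  double rad = 0.15 * (1.0 + std::sqrt(U0 * U0 + U1 * U1));
  const double TINY = 1e-30;
  double merit = std::sqrt(r0 * r0 + r1 * r1) / (Ts + TINY);
  double lambda = 1e-3;
  for (int it = 0; it < 40; ++it) {
    double h0 = 1e-6 * std::max(1.0, std::fabs(u0));
    double h1 = 1e-6 * std::max(1.0, std::fabs(u1));
    double a0, a1, c0, c1, td;
    if (junction_resid(u0 + h0, u1, VLV, VRV, P, ws, act, &a0, &a1, &td, NULL)) {
      h0 = -h0;
      if (junction_resid(u0 + h0, u1, VLV, VRV, P, ws, act, &a0, &a1, &td, NULL))
        break;
    }
    if (junction_resid(u0, u1 + h1, VLV, VRV, P, ws, act, &c0, &c1, &td, NULL)) {
      h1 = -h1;
      if (junction_resid(u0, u1 + h1, VLV, VRV, P, ws, act, &c0, &c1, &td, NULL))
        break;
    }
    double J00 = (a0 - r0) / h0, J10 = (a1 - r1) / h0;
    double J01 = (c0 - r0) / h1, J11 = (c1 - r1) / h1;
    // normal equations with Levenberg damping
    double A11 = J00 * J00 + J10 * J10, A12 = J00 * J01 + J10 * J11;
    double A22 = J01 * J01 + J11 * J11;
    double g0 = J00 * r0 + J10 * r1, g1 = J01 * r0 + J11 * r1;
    bool improved = false;
    for (int sub = 0; sub < 12; ++sub) {
      double B11 = A11 * (1 + lambda), B22 = A22 * (1 + lambda);
      double det = B11 * B22 - A12 * A12;
      if (std::fabs(det) < 1e-300) break;
      double d0 = (-g0 * B22 + g1 * A12) / det;
      double d1 = (-g1 * B11 + g0 * A12) / det;
      double t0 = u0 + d0, t1 = u1 + d1;
      double dd = std::sqrt((t0 - U0) * (t0 - U0) + (t1 - U1) * (t1 - U1));
      double q0, q1, qs;
      if (dd <= rad && t1 >= 0.3 * r_est &&
          !junction_resid(t0, t1, VLV, VRV, P, ws, act, &q0, &q1, &qs, NULL)) {
        double mq = std::sqrt(q0 * q0 + q1 * q1) / (qs + TINY);
        if (mq < merit) {
          u0 = t0; u1 = t1; r0 = q0; r1 = q1; Ts = qs; merit = mq;
          lambda = std::max(lambda * 0.3, 1e-6);
          improved = true;
          break;
        }
      }
      lambda *= 5.0;
    }
    if (!improved) break;
    if (merit < 1e-10) break;
  }
  if (junction_resid(u0, u1, VLV, VRV, P, ws, act, &r0, &r1, &Ts, go)) return 1;
  warm[0] = u0; warm[1] = u1;
  if (go) {
    go->VmS = u0; go->y = u1;
    go->PLV = 2 * std::fabs(go->Tm[0] * go->Cm[0]) * KPA2MMHG;
    go->PRV = 2 * std::fabs(go->Tm[2] * go->Cm[2]) * KPA2MMHG;
    go->resid = std::sqrt(r0 * r0 + r1 * r1);
  }
  return 0;
}

// Branch policy: a valid warm start is the physical-branch continuation and
// is the only start used while tracking a trajectory (a global search could
// converge to a contorted root of the force balance and poison the branch).
// The grid scan, restricted to physiological strains, is used on genuine
// cold starts only.
static int solve_junction(double VLV, double VRV, const double* P,
                          const double* ws, double act, double* warm,
                          GeoOut* go, int allow_grid, double tol = 1e-10) {
  if (warm[1] > 0 && std::isfinite(warm[0]) && std::isfinite(warm[1])) {
    if (!solve_junction_from(warm[0], warm[1], VLV, VRV, P, ws, act,
                             warm, go, tol))
      return 0;
  }
  if (!allow_grid) return 1;
  double u0, u1;
  junction_grid_start(VLV, VRV, P, ws, act, &u0, &u1);
  GeoOut tmp;
  if (solve_junction_from(u0, u1, VLV, VRV, P, ws, act, warm, &tmp, tol))
    return 1;
  double me = std::max(std::fabs(tmp.eps[0]),
                       std::max(std::fabs(tmp.eps[1]), std::fabs(tmp.eps[2])));
  if (me > 0.9) return 1;  // refuse a contorted branch
  if (go) *go = tmp;
  return 0;
}

// ---- circulation helpers ----
static inline double atrial_C(double t_beat, double period, const double* P) {
  double rel = mod_pos(t_beat / period - P[iT_onset], 1.0);
  if (rel < P[iD_a])
    return P[iCA_max] - (P[iCA_max] - P[iCA_min]) *
      0.5 * (1.0 - std::cos(2.0 * M_PI * rel / P[iD_a]));
  return P[iCA_max];
}
static inline double calcium_c(double t_beat, double period, const double* sp) {
  double t = mod_pos(t_beat, period);
  return sp[sCa_dia] + sp[sCa_amp] * (t / sp[sTau]) * std::exp(1.0 - t / sp[sTau]);
}
static inline double vflow(double up, double dn, double R) {
  double d = up - dn;
  return d > 0 ? d / R : 0.0;
}

// last successful geometry (freeze fallback across a transient fold)
static GeoOut g_geo_cache;
static int g_geo_valid = 0;
static int g_freezing = 0;
static double g_freeze_t0 = 0;

// ---- full system RHS; returns 0 on success ----
static int rhs(double t, const double* y, const double* P, double* warm,
               double* dy, double* out) {
  double VLV = y[6], VRV = y[7];
  if (VLV < -5.0 || VRV < -5.0) return 1;  // far outside the reachable set
  double period = 60.0 / P[iHR];
  double t_beat = mod_pos(t, period);

  GeoOut go;
  const double* ws = y + 8;
  // geometry needs a small positive cavity; outflow gating (below) keeps
  // the true volumes positive, this clamp only guards wild trial states
  double VLVg = std::max(VLV, 1.0), VRVg = std::max(VRV, 1.0);
  int solved = !solve_junction(VLVg, VRVg, P, ws, P[iACT], warm, &go,
                               !g_geo_valid);
  if (!solved && warm[1] > 0) {
    // the exact equilibrium transiently ceased to exist (fold): track the
    // least-imbalance configuration from the warm start
    solved = !track_junction_lsq(VLVg, VRVg, P, ws, P[iACT], warm, &go);
  }
  if (!solved) return 1;
  if (!std::isfinite(go.PLV) || !std::isfinite(go.PRV) ||
      go.PLV > 800.0 || go.PRV > 800.0) return 1;  // nonsense geometry
  g_geo_cache = go; g_geo_valid = 1; g_freezing = 0;

  double P_Ao = (y[0] - P[iV0_Ao]) / P[iC_Ao];
  double P_SV = (y[1] - P[iV0_SV]) / P[iC_SV];
  double P_PA = (y[2] - P[iV0_PA]) / P[iC_PA];
  double P_PV = (y[3] - P[iV0_PV]) / P[iC_PV];
  double C_at = atrial_C(t_beat, period, P);
  double P_LA = y[4] / C_at;
  double P_RA = y[5] / C_at;

  // an emptying cavity has nothing left to eject: smooth volume gating of
  // the outlet valves keeps cavity volumes strictly positive
  double gL = VLV > 0 ? VLV * VLV / (VLV * VLV + 9.0) : 0.0;
  double gR = VRV > 0 ? VRV * VRV / (VRV * VRV + 9.0) : 0.0;
  double q_av   = gL * vflow(go.PLV, P_Ao, P[iR_av]);
  double q_pval = gR * vflow(go.PRV, P_PA, P[iR_pval]);
  double q_mv   = vflow(P_LA, go.PLV, P[iR_mv]);
  double q_tv   = vflow(P_RA, go.PRV, P[iR_tv]);
  double q_sys  = (P_Ao - P_SV) / P[iSVR];
  double q_pul  = (P_PA - P_PV) / P[iPVR];
  double q_vs   = (P_SV - P_RA) / P[iR_ven_s];
  double q_vp   = (P_PV - P_LA) / P[iR_ven_p];

  dy[0] = q_av - q_sys;
  dy[1] = q_sys - q_vs;
  dy[2] = q_pval - q_pul;
  dy[3] = q_pul - q_vp;
  dy[4] = q_vp - q_mv;
  dy[5] = q_vs - q_tv;
  dy[6] = q_mv - q_av;
  dy[7] = q_tv - q_pval;

  for (int w = 0; w < 3; ++w) {
    const double* sp = P + iWALL0 + w * WBLK + 2;
    double Ca = calcium_c(t_beat, period, sp);
    double hn = sp[sHill];
    double can = std::pow(Ca, hn);
    double perm = can / (can + std::pow(sp[sCa50], hn));
    double A = std::min(std::max(y[8 + 3 * w + 1], 0.0), 1.0);
    double xb = y[8 + 3 * w + 2];
    double dA = sp[sF] * perm * (1.0 - A) - sp[sG] * A;
    double dxb = 0.5 * go.dLs[w] +
      (sp[sF] * perm * (1.0 - A) / std::max(A, 1e-3)) * (sp[sX0] - xb);
    dy[8 + 3 * w]     = go.dLs[w];
    dy[8 + 3 * w + 1] = dA;
    dy[8 + 3 * w + 2] = dxb;
  }

  if (out) {
    out[0] = P_Ao; out[1] = P_SV; out[2] = P_PA; out[3] = P_PV;
    out[4] = P_LA; out[5] = P_RA; out[6] = go.PLV; out[7] = go.PRV;
    out[8] = q_av; out[9] = q_pval; out[10] = q_mv; out[11] = q_tv;
    out[12] = q_sys; out[13] = q_pul; out[14] = q_vs; out[15] = q_vp;
    out[16] = go.VmS; out[17] = go.y;
  }
  return 0;
}

//' @noRd
// [[Rcpp::export]]
List c_solve_junction_dbg(double V_LV, double V_RV, NumericVector parms,
                          NumericVector wall_states, double act,
                          NumericVector warm) {
  double ws2[2] = { warm[0], warm[1] };
  GeoOut go;
  int st = solve_junction(V_LV, V_RV, parms.begin(), wall_states.begin(),
                          act, ws2, &go, 1);
  return List::create(_["status"] = st,
                      _["VmS"] = ws2[0], _["y"] = ws2[1],
                      _["resid"] = st ? NA_REAL : go.resid,
                      _["PLV"] = st ? NA_REAL : go.PLV,
                      _["PRV"] = st ? NA_REAL : go.PRV);
}

//' @noRd
// [[Rcpp::export]]
List c_rhs(double t, NumericVector y, NumericVector parms, NumericVector warm) {
  if (y.size() != NSTATE) stop("state must have length %d", NSTATE);
  if (parms.size() != NPAR) stop("parms must have length %d", NPAR);
  double ws[2] = { warm[0], warm[1] };
  std::vector<double> dy(NSTATE), out(NOUT);
  int st = rhs(t, y.begin(), parms.begin(), ws, dy.data(), out.data());
  if (st) stop("compiled RHS failed (geometry solver or unphysical state)");
  return List::create(_["derivatives"] = NumericVector(dy.begin(), dy.end()),
                      _["outputs"] = NumericVector(out.begin(), out.end()),
                      _["warm"] = NumericVector::create(ws[0], ws[1]));
}

// ---- Cash-Karp RK45 ----
static const double b21 = 0.2;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
static const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
                    b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
                    c6 = 512.0 / 1771.0;
static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
                    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                    dc6 = c6 - 0.25;

// one adaptive step from t with suggested dt; returns achieved dt (>0) or
// -1 on hard failure. y updated in place.
static double rk_step(double& t, double* y, const double* P, double* warm,
                      double rtol, double atol, double dt, double dt_min) {
  std::vector<double> k1(NSTATE), k2(NSTATE), k3(NSTATE), k4(NSTATE),
    k5(NSTATE), k6(NSTATE), yt(NSTATE), y5(NSTATE);
  if (rhs(t, y, P, warm, k1.data(), NULL)) return -1;
  double warm_save[2] = { warm[0], warm[1] };
  for (int tries = 0; tries < 60; ++tries) {
    // wild trial stages can drag the geometry warm start into another
    // basin; keep each attempt anchored at the step-start solution
    warm[0] = warm_save[0]; warm[1] = warm_save[1];
    bool fail = false;
    for (int i = 0; i < NSTATE; ++i) yt[i] = y[i] + dt * b21 * k1[i];
    fail = rhs(t + 0.2 * dt, yt.data(), P, warm, k2.data(), NULL);
    if (!fail) {
      for (int i = 0; i < NSTATE; ++i)
        yt[i] = y[i] + dt * (b31 * k1[i] + b32 * k2[i]);
      fail = rhs(t + 0.3 * dt, yt.data(), P, warm, k3.data(), NULL);
    }
    if (!fail) {
      for (int i = 0; i < NSTATE; ++i)
        yt[i] = y[i] + dt * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
      fail = rhs(t + 0.6 * dt, yt.data(), P, warm, k4.data(), NULL);
    }
    if (!fail) {
      for (int i = 0; i < NSTATE; ++i)
        yt[i] = y[i] + dt * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
      fail = rhs(t + dt, yt.data(), P, warm, k5.data(), NULL);
    }
    if (!fail) {
      for (int i = 0; i < NSTATE; ++i)
        yt[i] = y[i] + dt * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                             b64 * k4[i] + b65 * k5[i]);
      fail = rhs(t + 0.875 * dt, yt.data(), P, warm, k6.data(), NULL);
    }
    double err = 0;
    if (!fail) {
      for (int i = 0; i < NSTATE; ++i) {
        y5[i] = y[i] + dt * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
        double ei = dt * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] +
                          dc5 * k5[i] + dc6 * k6[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
        err = std::max(err, std::fabs(ei) / sc);
      }
      if (!std::isfinite(err)) fail = true;
    }
    if (!fail && err <= 1.0) {
      // confirm the proposed state itself is solvable (the combination y5
      // is never evaluated by the stages); reject the step otherwise
      std::vector<double> kchk(NSTATE);
      fail = rhs(t + dt, y5.data(), P, warm, kchk.data(), NULL);
      if (!fail) {
        t += dt;
        std::copy(y5.begin(), y5.end(), y);
        double fac = (err > 1e-12) ? 0.9 * std::pow(err, -0.2) : 5.0;
        fac = std::min(5.0, std::max(0.2, fac));
        return dt * fac;   // suggested next dt, achieved step was dt
      }
    }
    dt *= fail ? 0.25 : std::min(0.9, std::max(0.1, 0.9 * std::pow(err, -0.25)));
    if (dt < dt_min) return -1;
  }
  return -1;
}

//' @noRd
// [[Rcpp::export]]
List c_integrate(NumericVector y0, double t0, double t_end, int nsamp,
                 NumericVector parms, NumericVector warm,
                 double rtol, double atol) {
  if (y0.size() != NSTATE) stop("state must have length %d", NSTATE);
  if (parms.size() != NPAR) stop("parms must have length %d", NPAR);
  if (nsamp < 2) stop("nsamp must be >= 2");
  const double* P = parms.begin();
  double ws[2] = { warm[0], warm[1] };
  // the freeze cache persists across beats of one run; reset on cold start
  if (!(warm[1] > 0)) { g_geo_valid = 0; g_freezing = 0; }
  std::vector<double> y(y0.begin(), y0.end());

  NumericMatrix traj(nsamp + 1, 1 + NSTATE + NOUT);
  std::vector<double> out(NOUT), dyd(NSTATE);

  double t = t0;
  double span = t_end - t0;
  double dt = span / (nsamp * 4.0);
  double dt_min = span * 1e-12;

  // record initial sample
  if (rhs(t, y.data(), P, ws, dyd.data(), out.data()))
    stop("integration failed at t=%g (initial state)", t);
  traj(0, 0) = t;
  for (int i = 0; i < NSTATE; ++i) traj(0, 1 + i) = y[i];
  for (int i = 0; i < NOUT; ++i) traj(0, 1 + NSTATE + i) = out[i];

  for (int sm = 1; sm <= nsamp; ++sm) {
    double t_target = t0 + span * sm / nsamp;
    while (t < t_target - 1e-12 * span) {
      double step = std::min(dt, t_target - t);
      double nxt = rk_step(t, y.data(), P, ws, rtol, atol, step, dt_min);
      if (nxt < 0)
        stop("integration failed at t=%g (step size underflow)", t);
      if (step >= dt) dt = nxt;   // only grow suggestion from full steps
    }
    if (rhs(t, y.data(), P, ws, dyd.data(), out.data()))
      stop("integration failed at sample t=%g", t);
    traj(sm, 0) = t;
    for (int i = 0; i < NSTATE; ++i) traj(sm, 1 + i) = y[i];
    for (int i = 0; i < NOUT; ++i) traj(sm, 1 + NSTATE + i) = out[i];
  }

  return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                      _["traj"] = traj,
                      _["warm"] = NumericVector::create(ws[0], ws[1]));
}
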