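#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Seven-compartment model of IDU initiation with OAT stratification.
//
// State layout: y[0..6] = G, V, A, B, C, D, E
//   G  not using illicit drugs (excluding cannabis)
//   V  using illicit drugs other than / in addition to cannabis, injection-naive
//   A  PWID, no assisting history, not on OAT
//   B  PWID, assisting history, not on OAT
//   C  PWID, no assisting history, on OAT
//   D  PWID, assisting history, on OAT
//   E  former PWID (permanent cessation)
//
// Parameter vector layout (must match .rate_vector() on the R side):
//   0 mu_B, 1 mu_OV, 2 theta, 3 xi, 4 xi_oat, 5 rho, 6 m, 7 RR_I, 8 RR_OAT,
//   9 RR_OATov, 10 beta, 11 gamma, 12 tau, 13 alpha, 14 delta_enter,
//   15 delta_exit, 16 tau_vmin, 17 literal_dB (0/1)
//
// Ten instantaneous event fluxes are accumulated alongside the state:
//   0 assisted initiations        1 unassisted initiations
//   2 A->B history transitions    3 C->D history transitions
//   4 OAT entries (alpha*(A+B))   5 OAT exits (rho*(C+D))
//   6 cessations (flow into E)    7 baseline deaths (mu_B*N)
//   8 overdose deaths             9 OAT-transition excess deaths

static const int NSTATE = 7;
static const int NFLUX = 10;
static const int NDIM = NSTATE + NFLUX;

static inline void idu_rhs(const double *y, const double *p, double *dy) {
  const double muB = p[0], muOV = p[1], theta = p[2], xi = p[3], xiOAT = p[4],
               rho = p[5], m = p[6], RRI = p[7], RROAT = p[8], RROATov = p[9],
               beta = p[10], gamma = p[11], tau = p[12], alpha = p[13],
               dEnter = p[14], dExit = p[15], vmin = p[16];
  const bool literal_dB = p[17] != 0.0;

  const double G = y[0], V = y[1], A = y[2], B = y[3], C = y[4], D = y[5],
               E = y[6];
  const double N = G + V + A + B + C + D + E;

  const double force = beta * (A + RRI * B + RROAT * C + RRI * RROAT * D) / N;
  const double assisted = force * V;
  double avail = (vmin > 0.0) ? V / vmin : 1.0;
  if (avail > 1.0) avail = 1.0;
  if (avail < 0.0) avail = 0.0;
  const double unassisted = tau * avail;

  const double gAB = m * beta * A / N * V;        // A -> B (newly assisting)
  const double gCD = m * beta * RROAT * C / N * V; // C -> D
  const double sigma = muB * N; // births replace all non-overdose deaths

  const double oatInA = alpha * A, oatInB = alpha * B;
  const double oatOutC = rho * C, oatOutD = rho * D;

  // cessation out of B: the published equations print xi*V here, which breaks
  // the bookkeeping; the default reading applies xi to B itself.
  const double cessB = literal_dB ? xi * V : xi * B;
  const double cessE = literal_dB ? xi * (A + B) + xiOAT * (C + D)
                                  : xi * A + cessB + xiOAT * (C + D);

  dy[0] = sigma - theta * G + gamma * V - muB * G;
  dy[1] = theta * G - gamma * V - assisted - unassisted - muB * V;
  dy[2] = assisted + unassisted - gAB - oatInA + oatOutC * (1.0 - dExit) -
          xi * A - (muB + muOV) * A;
  dy[3] = gAB - oatInB + oatOutD * (1.0 - dExit) - cessB - (muB + muOV) * B;
  dy[4] = oatInA * (1.0 - dEnter) - oatOutC - gCD - xiOAT * C -
          (muB + RROATov * muOV) * C;
  dy[5] = oatInB * (1.0 - dEnter) + gCD - oatOutD - xiOAT * D -
          (muB + RROATov * muOV) * D;
  dy[6] = cessE - muB * E;

  dy[7] = assisted;
  dy[8] = unassisted;
  dy[9] = gAB;
  dy[10] = gCD;
  dy[11] = oatInA + oatInB;
  dy[12] = oatOutC + oatOutD;
  dy[13] = cessE;
  dy[14] = sigma; // baseline deaths equal the replacement inflow mu_B*N
  dy[15] = muOV * (A + B) + RROATov * muOV * (C + D);
  dy[16] = dEnter * (oatInA + oatInB) + dExit * (oatOutC + oatOutD);
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

//' @keywords internal
// [[Rcpp::export(name = ".rk45_idu")]]
NumericMatrix rk45_idu(NumericVector y0, NumericVector pars,
                       NumericVector times, double rtol, double atol,
                       double neg_tol) {
  if (y0.size() != NSTATE) stop("state vector must have 7 components");
  if (pars.size() != 18) stop("parameter vector must have 18 components");
  const int nt = times.size();
  if (nt < 2) stop("need at least two output times");

  double y[NDIM], ytmp[NDIM], ynew[NDIM];
  double k1[NDIM], k2[NDIM], k3[NDIM], k4[NDIM], k5[NDIM], k6[NDIM], k7[NDIM];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];
  for (int i = NSTATE; i < NDIM; ++i) y[i] = 0.0;
  const double *p = pars.begin();

  NumericMatrix out(nt, NDIM + 1);
  out(0, 0) = times[0];
  for (int i = 0; i < NDIM; ++i) out(0, i + 1) = y[i];

  double t = times[0];
  double h_next = (times[nt - 1] - times[0]) / 100.0;
  if (h_next <= 0) stop("times must be strictly increasing");
  long nstep = 0;
  const long maxstep = 5000000;
  idu_rhs(y, p, k1);

  for (int it = 1; it < nt; ++it) {
    const double tend = times[it];
    if (tend <= t) stop("times must be strictly increasing");
    const double teps = 1e-12 * std::max(1.0, std::fabs(tend));
    while (t < tend - teps) {
      if (++nstep > maxstep) stop("rk45: maximum step count exceeded");
      double h = h_next;
      bool hit_end = false;
      if (t + h >= tend) {
        h = tend - t;
        hit_end = true;
      }
      for (int i = 0; i < NDIM; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      idu_rhs(ytmp, p, k2);
      for (int i = 0; i < NDIM; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      idu_rhs(ytmp, p, k3);
      for (int i = 0; i < NDIM; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      idu_rhs(ytmp, p, k4);
      for (int i = 0; i < NDIM; ++i)
        ytmp[i] =
            y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      idu_rhs(ytmp, p, k5);
      for (int i = 0; i < NDIM; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      idu_rhs(ytmp, p, k6);
      for (int i = 0; i < NDIM; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      idu_rhs(ynew, p, k7);

      double err = 0.0;
      for (int i = 0; i < NDIM; ++i) {
        const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                               e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        const double sc =
            atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        const double r = ei / sc;
        err += r * r;
      }
      err = std::sqrt(err / NDIM);

      double fac = (err > 1e-12) ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;

      if (err <= 1.0) { // accept
        t += h;
        for (int i = 0; i < NDIM; ++i) y[i] = ynew[i];
        // clamp tiny negative compartments; abort on real negativity
        for (int i = 0; i < NSTATE; ++i) {
          if (y[i] < 0.0) {
            if (y[i] < -neg_tol)
              stop("rk45: compartment %d went negative (%g) at t=%g", i + 1,
                   y[i], t);
            y[i] = 0.0;
          }
        }
        for (int i = 0; i < NDIM; ++i) k1[i] = k7[i]; // FSAL
        // do not let a boundary-truncated step shrink the working step size
        if (!hit_end) h_next = h * fac;
        if (hit_end) break;
      } else { // reject; k1 remains valid at (t, y)
        h_next = h * fac;
        if (h_next < 1e-12) stop("rk45: step size underflow at t=%g", t);
      }
    }
    out(it, 0) = t;
    for (int i = 0; i < NDIM; ++i) out(it, i + 1) = y[i];
  }
  return out;
}

//' @keywords internal
// [[Rcpp::export(name = ".idu_rhs_cpp")]]
NumericVector idu_rhs_cpp(NumericVector y, NumericVector pars) {
  if (pars.size() != 18) stop("parameter vector must have 18 components");
  double yy[NDIM], dy[NDIM];
  for (int i = 0; i < NSTATE; ++i) yy[i] = y[i];
  for (int i = NSTATE; i < NDIM; ++i) yy[i] = 0.0;
  idu_rhs(yy, pars.begin(), dy);
  NumericVector out(NDIM);
  for (int i = 0; i < NDIM; ++i) out[i] = dy[i];
  return out;
}
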