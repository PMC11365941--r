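// Core integrator for the 1-D spine resource model.
//
// Fields on a uniform grid: C (fast potentiating resource), Pin (inactive
// slow resource), P (active slow resource), S (normalised spine size).
//
//   dC/dt   = alpha1 C_xx - alpha2 C
//   dPin/dt = beta1 Pin_xx - beta2 Pin C
//   dP/dt   = beta1 P_xx + beta2 C Pin - gamma P
//   dS/dt   = zeta1 C + zeta2 P F(S),  F(S) = -tanh(phi (S - nu))
//
// Scheme: Strang splitting R(dt/2) D(dt) R(dt/2); diffusion by
// Crank-Nicolson with a conservative zero-flux (Neumann) stencil, reactions
// by the explicit midpoint rule. Second order in dt; the Neumann stencil
// has zero column sums so sum(Pin + P) is conserved exactly when gamma = 0.
//
// rd_adjoint() implements the discrete adjoint of exactly this scheme, so
// its gradient matches finite differences of rd_integrate() to rounding.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Prefactored constant symmetric tridiagonal solver (Thomas algorithm).
// A has diagonal d0 (boundary rows) / d1 (interior rows) and off-diagonal e.
struct TriSolver {
  int n;
  double e;
  std::vector<double> cp;   // modified super-diagonal
  std::vector<double> inv;  // 1 / (pivot)
  void init(int n_, double d_bnd, double d_int, double e_) {
    n = n_;
    e = e_;
    cp.assign(n, 0.0);
    inv.assign(n, 0.0);
    double piv = d_bnd;
    inv[0] = 1.0 / piv;
    cp[0] = e / piv;
    for (int i = 1; i < n; ++i) {
      double d = (i == n - 1) ? d_bnd : d_int;
      piv = d - e * cp[i - 1];
      inv[i] = 1.0 / piv;
      cp[i] = e / piv;
    }
  }
  void solve(std::vector<double>& x) const {
    x[0] *= inv[0];
    for (int i = 1; i < n; ++i) x[i] = (x[i] - e * x[i - 1]) * inv[i];
    for (int i = n - 2; i >= 0; --i) x[i] -= cp[i] * x[i + 1];
  }
};

// y <- B x where B = I + (r/2) L with the conservative Neumann Laplacian.
void applyB(const std::vector<double>& x, std::vector<double>& y, double r, int n) {
  double h = 0.5 * r;
  y[0] = (1.0 - h) * x[0] + h * x[1];
  for (int i = 1; i < n - 1; ++i)
    y[i] = h * x[i - 1] + (1.0 - 2.0 * h) * x[i] + h * x[i + 1];
  y[n - 1] = h * x[n - 2] + (1.0 - h) * x[n - 1];
}

// y <- L x (Neumann Laplacian, unscaled).
void applyL(const std::vector<double>& x, std::vector<double>& y, int n) {
  y[0] = x[1] - x[0];
  for (int i = 1; i < n - 1; ++i) y[i] = x[i - 1] - 2.0 * x[i] + x[i + 1];
  y[n - 1] = x[n - 2] - x[n - 1];
}

struct Pars {
  double alpha1, alpha2, beta1, beta2, gamma, phi, nu, zeta1, zeta2;
};

inline Pars unpack(const NumericVector& p) {
  Pars q;
  q.alpha1 = p[0]; q.alpha2 = p[1]; q.beta1 = p[2]; q.beta2 = p[3];
  q.gamma = p[4]; q.phi = p[5]; q.nu = p[6]; q.zeta1 = p[7]; q.zeta2 = p[8];
  return q;
}

// Pointwise reaction right-hand side.
inline void rhs(const Pars& q, double C, double Pin, double P, double S,
                double& fC, double& fPin, double& fP, double& fS) {
  double F = -std::tanh(q.phi * (S - q.nu));
  fC = -q.alpha2 * C;
  fPin = -q.beta2 * Pin * C;
  fP = q.beta2 * C * Pin - q.gamma * P;
  fS = q.zeta1 * C + q.zeta2 * P * F;
}

// Explicit midpoint reaction step of length tau, in place.
void reactionStep(const Pars& q, double tau, std::vector<double>& C,
                  std::vector<double>& Pin, std::vector<double>& P,
                  std::vector<double>& S) {
  int n = (int)C.size();
  double fC, fPin, fP, fS;
  for (int i = 0; i < n; ++i) {
    rhs(q, C[i], Pin[i], P[i], S[i], fC, fPin, fP, fS);
    double mC = C[i] + 0.5 * tau * fC;
    double mPin = Pin[i] + 0.5 * tau * fPin;
    double mP = P[i] + 0.5 * tau * fP;
    double mS = S[i] + 0.5 * tau * fS;
    rhs(q, mC, mPin, mP, mS, fC, fPin, fP, fS);
    C[i] += tau * fC;
    Pin[i] += tau * fPin;
    P[i] += tau * fP;
    S[i] += tau * fS;
  }
}

// J(u)^T psi at one point.
inline void jacT(const Pars& q, double C, double Pin, double P, double S,
                 double pC, double pPin, double pP, double pS,
                 double& oC, double& oPin, double& oP, double& oS) {
  double qarg = q.phi * (S - q.nu);
  double sech2 = 1.0 / std::cosh(qarg); sech2 *= sech2;
  double F = -std::tanh(qarg);
  double Fp = -q.phi * sech2;
  oC = -q.alpha2 * pC - q.beta2 * Pin * pPin + q.beta2 * Pin * pP + q.zeta1 * pS;
  oPin = -q.beta2 * C * pPin + q.beta2 * C * pP;
  oP = -q.gamma * pP + q.zeta2 * F * pS;
  oS = q.zeta2 * P * Fp * pS;
}

// Accumulate phi^T df/dtheta at one point into g[9] with weight w.
// Parameter order: alpha1 alpha2 beta1 beta2 gamma phi nu zeta1 zeta2
// (alpha1 and beta1 are handled in the diffusion sub-step).
inline void accumFtheta(const Pars& q, double C, double Pin, double P, double S,
                        double pC, double pPin, double pP, double pS,
                        double w, double* g) {
  double qarg = q.phi * (S - q.nu);
  double sech2 = 1.0 / std::cosh(qarg); sech2 *= sech2;
  double F = -std::tanh(qarg);
  g[1] += w * pC * (-C);
  g[3] += w * (pPin * (-Pin * C) + pP * (Pin * C));
  g[4] += w * pP * (-P);
  g[5] += w * pS * q.zeta2 * P * (-(S - q.nu) * sech2);
  g[6] += w * pS * q.zeta2 * P * (q.phi * sech2);
  g[7] += w * pS * C;
  g[8] += w * pS * P * F;
}

}  // namespace

// [[Rcpp::export(name = ".rd_integrate")]]
List rd_integrate(NumericVector C0, NumericVector Pin0, NumericVector P0,
                  NumericVector S0, double dx, double dt, int nsteps,
                  NumericVector pars, IntegerVector snap_steps,
                  IntegerVector spine_nodes, bool store_fields) {
  int n = C0.size();
  Pars q = unpack(pars);
  std::vector<double> C(C0.begin(), C0.end()), Pin(Pin0.begin(), Pin0.end()),
      P(P0.begin(), P0.end()), S(S0.begin(), S0.end()), tmp(n);

  double rC = q.alpha1 * dt / (dx * dx);
  double rP = q.beta1 * dt / (dx * dx);
  TriSolver tC, tP;
  tC.init(n, 1.0 + 0.5 * rC, 1.0 + rC, -0.5 * rC);
  tP.init(n, 1.0 + 0.5 * rP, 1.0 + rP, -0.5 * rP);

  int nsnap = snap_steps.size(), nsp = spine_nodes.size();
  NumericMatrix outS(nsp, nsnap), outC(nsp, nsnap), outP(nsp, nsnap),
      outPin(nsp, nsnap);
  NumericMatrix fC, fPin, fP, fS;
  if (store_fields) {
    fC = NumericMatrix(n, nsnap); fPin = NumericMatrix(n, nsnap);
    fP = NumericMatrix(n, nsnap); fS = NumericMatrix(n, nsnap);
  }
  int isnap = 0;
  auto record = [&](int step) {
    while (isnap < nsnap && snap_steps[isnap] == step) {
      for (int k = 0; k < nsp; ++k) {
        int j = spine_nodes[k];
        outS(k, isnap) = S[j]; outC(k, isnap) = C[j];
        outP(k, isnap) = P[j]; outPin(k, isnap) = Pin[j];
      }
      if (store_fields)
        for (int i = 0; i < n; ++i) {
          fC(i, isnap) = C[i]; fPin(i, isnap) = Pin[i];
          fP(i, isnap) = P[i]; fS(i, isnap) = S[i];
        }
      ++isnap;
    }
  };
  record(0);

  for (int step = 1; step <= nsteps; ++step) {
    reactionStep(q, 0.5 * dt, C, Pin, P, S);
    applyB(C, tmp, rC, n); C = tmp; tC.solve(C);
    applyB(Pin, tmp, rP, n); Pin = tmp; tP.solve(Pin);
    applyB(P, tmp, rP, n); P = tmp; tP.solve(P);
    reactionStep(q, 0.5 * dt, C, Pin, P, S);
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(C[i]) || !std::isfinite(Pin[i]) ||
          !std::isfinite(P[i]) || !std::isfinite(S[i]))
        stop("non-finite field value at t = %f min (step %d)", step * dt, step);
    record(step);
  }

  List out = List::create(_["S"] = outS, _["C"] = outC, _["P"] = outP,
                          _["Pin"] = outPin);
  if (store_fields) {
    out["field_C"] = fC; out["field_Pin"] = fPin;
    out["field_P"] = fP; out["field_S"] = fS;
  }
  return out;
}

// Forward pass with full state storage, then discrete adjoint backward pass.
// Cost: sum over snapshots s and spines k of (S[node_k] - target(k, s))^2.
// Returns cost, gradient wrt the 9 dynamic parameters, and the adjoint of
// the initial fields (for chaining to initial-condition parameters).
// [[Rcpp::export(name = ".rd_adjoint")]]
List rd_adjoint(NumericVector C0, NumericVector Pin0, NumericVector P0,
                NumericVector S0, double dx, double dt, int nsteps,
                NumericVector pars, IntegerVector snap_steps,
                IntegerVector spine_nodes, NumericMatrix target) {
  int n = C0.size();
  Pars q = unpack(pars);
  int nsnap = snap_steps.size(), nsp = spine_nodes.size();

  double rC = q.alpha1 * dt / (dx * dx);
  double rP = q.beta1 * dt / (dx * dx);
  TriSolver tC, tP;
  tC.init(n, 1.0 + 0.5 * rC, 1.0 + rC, -0.5 * rC);
  tP.init(n, 1.0 + 0.5 * rP, 1.0 + rP, -0.5 * rP);

  // Forward pass, storing the state at the start of every step.
  std::vector<double> store((size_t)(nsteps + 1) * 4 * n);
  std::vector<double> C(C0.begin(), C0.end()), Pin(Pin0.begin(), Pin0.end()),
      P(P0.begin(), P0.end()), S(S0.begin(), S0.end()), tmp(n);
  auto save = [&](int step) {
    double* d = &store[(size_t)step * 4 * n];
    std::copy(C.begin(), C.end(), d);
    std::copy(Pin.begin(), Pin.end(), d + n);
    std::copy(P.begin(), P.end(), d + 2 * n);
    std::copy(S.begin(), S.end(), d + 3 * n);
  };
  save(0);
  for (int step = 1; step <= nsteps; ++step) {
    reactionStep(q, 0.5 * dt, C, Pin, P, S);
    applyB(C, tmp, rC, n); C = tmp; tC.solve(C);
    applyB(Pin, tmp, rP, n); Pin = tmp; tP.solve(Pin);
    applyB(P, tmp, rP, n); P = tmp; tP.solve(P);
    reactionStep(q, 0.5 * dt, C, Pin, P, S);
    save(step);
  }

  // Cost and model output.
  NumericMatrix modelS(nsp, nsnap);
  double cost = 0.0;
  for (int s = 0; s < nsnap; ++s) {
    const double* Ssnap = &store[(size_t)snap_steps[s] * 4 * n] + 3 * n;
    for (int k = 0; k < nsp; ++k) {
      double m = Ssnap[spine_nodes[k]];
      modelS(k, s) = m;
      double e = m - target(k, s);
      cost += e * e;
    }
  }

  // Backward pass.
  std::vector<double> pC(n, 0.0), pPin(n, 0.0), pP(n, 0.0), pS(n, 0.0);
  std::vector<double> a(4 * n), b(4 * n), w(n), lx(n), v(4);
  double g[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  int isnap = nsnap - 1;
  double tau = 0.5 * dt;

  // Adjoint of one reaction half-step with stored input y (in arrays
  // yC.. at offset), accumulating parameter gradient.
  auto reactionAdj = [&](const double* yC, const double* yPin,
                         const double* yP, const double* yS) {
    double fC, fPin, fP, fS;
    for (int i = 0; i < n; ++i) {
      rhs(q, yC[i], yPin[i], yP[i], yS[i], fC, fPin, fP, fS);
      double mC = yC[i] + 0.5 * tau * fC, mPin = yPin[i] + 0.5 * tau * fPin;
      double mP = yP[i] + 0.5 * tau * fP, mS = yS[i] + 0.5 * tau * fS;
      // v = tau * J(m)^T psi
      double vC, vPin, vP, vS;
      jacT(q, mC, mPin, mP, mS, pC[i], pPin[i], pP[i], pS[i], vC, vPin, vP, vS);
      vC *= tau; vPin *= tau; vP *= tau; vS *= tau;
      // grad += tau psi^T f_theta(m) + (tau/2) v^T f_theta(y)
      accumFtheta(q, mC, mPin, mP, mS, pC[i], pPin[i], pP[i], pS[i], tau, g);
      accumFtheta(q, yC[i], yPin[i], yP[i], yS[i], vC, vPin, vP, vS, 0.5 * tau, g);
      // psi_in = psi + v + (tau/2) J(y)^T v
      double uC, uPin, uP, uS;
      jacT(q, yC[i], yPin[i], yP[i], yS[i], vC, vPin, vP, vS, uC, uPin, uP, uS);
      pC[i] += vC + 0.5 * tau * uC;
      pPin[i] += vPin + 0.5 * tau * uPin;
      pP[i] += vP + 0.5 * tau * uP;
      pS[i] += vS + 0.5 * tau * uS;
    }
  };

  for (int step = nsteps; step >= 1; --step) {
    // inject cost adjoint at snapshot states
    while (isnap >= 0 && snap_steps[isnap] == step) {
      const double* Ssnap = &store[(size_t)step * 4 * n] + 3 * n;
      for (int k = 0; k < nsp; ++k) {
        int j = spine_nodes[k];
        pS[j] += 2.0 * (Ssnap[j] - target(k, isnap));
      }
      --isnap;
    }
    // recompute intermediates of this step from the stored start state
    const double* y0 = &store[(size_t)(step - 1) * 4 * n];
    std::copy(y0, y0 + n, a.begin());
    std::copy(y0 + n, y0 + 2 * n, a.begin() + n);
    std::copy(y0 + 2 * n, y0 + 3 * n, a.begin() + 2 * n);
    std::copy(y0 + 3 * n, y0 + 4 * n, a.begin() + 3 * n);
    {
      std::vector<double> aC(a.begin(), a.begin() + n),
          aPin(a.begin() + n, a.begin() + 2 * n),
          aP(a.begin() + 2 * n, a.begin() + 3 * n),
          aS(a.begin() + 3 * n, a.end());
      reactionStep(q, tau, aC, aPin, aP, aS);  // state after R1
      std::copy(aC.begin(), aC.end(), a.begin());
      std::copy(aPin.begin(), aPin.end(), a.begin() + n);
      std::copy(aP.begin(), aP.end(), a.begin() + 2 * n);
      std::copy(aS.begin(), aS.end(), a.begin() + 3 * n);
      // state after diffusion
      applyB(aC, w, rC, n); tC.solve(w); std::copy(w.begin(), w.end(), b.begin());
      applyB(aPin, w, rP, n); tP.solve(w); std::copy(w.begin(), w.end(), b.begin() + n);
      applyB(aP, w, rP, n); tP.solve(w); std::copy(w.begin(), w.end(), b.begin() + 2 * n);
      std::copy(aS.begin(), aS.end(), b.begin() + 3 * n);
    }
    // adjoint of R2 at input b
    reactionAdj(&b[0], &b[n], &b[2 * n], &b[3 * n]);
    // adjoint of diffusion: psi_in = B A^{-1} psi_out (symmetric A, B);
    // grad_r += (dt/(2 dx^2)) w^T L (u_in + u_out) with w = A^{-1} psi_out.
    double sc = dt / (2.0 * dx * dx);
    {  // C field (alpha1)
      std::copy(pC.begin(), pC.end(), w.begin()); tC.solve(w);
      for (int i = 0; i < n; ++i) tmp[i] = a[i] + b[i];
      applyL(tmp, lx, n);
      for (int i = 0; i < n; ++i) g[0] += sc * w[i] * lx[i];
      applyB(w, pC, rC, n);
    }
    {  // Pin field (beta1)
      std::copy(pPin.begin(), pPin.end(), w.begin()); tP.solve(w);
      for (int i = 0; i < n; ++i) tmp[i] = a[n + i] + b[n + i];
      applyL(tmp, lx, n);
      for (int i = 0; i < n; ++i) g[2] += sc * w[i] * lx[i];
      applyB(w, pPin, rP, n);
    }
    {  // P field (beta1)
      std::copy(pP.begin(), pP.end(), w.begin()); tP.solve(w);
      for (int i = 0; i < n; ++i) tmp[i] = a[2 * n + i] + b[2 * n + i];
      applyL(tmp, lx, n);
      for (int i = 0; i < n; ++i) g[2] += sc * w[i] * lx[i];
      applyB(w, pP, rP, n);
    }
    // adjoint of R1 at input y0
    reactionAdj(y0, y0 + n, y0 + 2 * n, y0 + 3 * n);
  }

  return List::create(
      _["cost"] = cost, _["grad_dyn"] = NumericVector(g, g + 9),
      _["model_S"] = modelS,
      _["psi_C0"] = NumericVector(pC.begin(), pC.end()),
      _["psi_Pin0"] = NumericVector(pPin.begin(), pPin.end()),
      _["psi_P0"] = NumericVector(pP.begin(), pP.end()),
      _["psi_S0"] = NumericVector(pS.begin(), pS.end()));
}
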