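// Two-population diffusion approximation of the joint allele-frequency
// density phi(x, y): drift with relative sizes (nu1, nu2), symmetric
// migration advection, and new-mutation influx at the low-frequency corner.
// Integrated by operator splitting with an implicit (tridiagonal) sweep per
// direction on a boundary-crowded grid; zero-flux outer boundaries let mass
// accumulate in the loss/fixation classes.  Time in units of 2*N_ref
// generations, migration in units of 2*N_ref*m, matching the coalescent
// simulator.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One implicit sweep of the 1-D operator
//   dphi/dt = -d/dx[ a(x) phi ] + (1/2) d^2/dx^2 [ V(x) phi ]
// applied to every row (or column) of phi.  'along_x = true' sweeps in the
// first index.  adv_coef gives a(x) = mig * (other - x).
static void sweep(NumericMatrix &phi, const std::vector<double> &xx,
                  double nu, double mig, double dt, bool along_x) {
  int G = xx.size();
  std::vector<double> dx(G - 1), Delta(G), V(G);
  for (int j = 0; j < G - 1; ++j) dx[j] = xx[j + 1] - xx[j];
  Delta[0] = dx[0] / 2.0; Delta[G - 1] = dx[G - 2] / 2.0;
  for (int j = 1; j < G - 1; ++j) Delta[j] = (xx[j + 1] - xx[j - 1]) / 2.0;
  for (int j = 0; j < G; ++j) V[j] = xx[j] * (1.0 - xx[j]) / nu;

  std::vector<double> a(G), b(G), c(G), r(G), cp(G), dp(G);

  for (int k = 0; k < G; ++k) {           // k indexes the passive direction
    double other = xx[k];
    // flux F_{j+1/2} = A_j * [(1-d_j) phi_j + d_j phi_{j+1}]
    //                  - (V_{j+1} phi_{j+1} - V_j phi_j) / (2 dx_j)
    // phi_j' = -(F_{j+1/2} - F_{j-1/2}) / Delta_j
    for (int j = 0; j < G; ++j) { a[j] = 0.0; b[j] = 1.0; c[j] = 0.0; }
    for (int j = 0; j < G - 1; ++j) {
      double xm = 0.5 * (xx[j] + xx[j + 1]);
      double A = mig * (other - xm);
      double Vm = 0.5 * (V[j] + V[j + 1]);
      // Flux written in psi = V*phi, which is smooth (~ theta*(1-x)) on the
      // singular neutral profile phi ~ theta/x, so the advective divergence
      // vanishes identically there:
      //   F = (A/Vm) [(1-d) psi_j + d psi_{j+1}] - (psi_{j+1}-psi_j)/(2 dx)
      // with the Scharfetter-Gummel weight d = 1/w - 1/(e^w - 1),
      // w = 2 A dx / Vm (0.5 as w -> 0, full upwinding in either limit).
      double del, r;
      if (Vm <= 0.0) { del = 0.5; r = 0.0; }
      else {
        r = A / Vm;
        double w = 2.0 * A * dx[j] / Vm;
        if (std::fabs(w) < 1e-8) del = 0.5;
        else if (w > 500.0) del = 1.0 / w;
        else if (w < -500.0) del = 1.0 + 1.0 / w;
        else del = 1.0 / w - 1.0 / std::expm1(w);
      }
      double coef_j  = V[j] * (r * (1.0 - del) + 1.0 / (2.0 * dx[j]));
      double coef_j1 = V[j + 1] * (r * del - 1.0 / (2.0 * dx[j]));
      // Boundary nodes have V = 0, so the psi-form drops their advective
      // exchange entirely.  Restore it with the plain velocity * density
      // term, but only when the velocity points into the domain (export of
      // variants private to one population, reintroduction of locally
      // extinct variants): the mass parked on a boundary cannot be advected
      // further outward, and letting it would drain the neighbouring live
      // cells in proportion to the (large) absorbed pile.
      if (V[j] == 0.0 && A > 0.0)     coef_j  += A * (1.0 - del);
      if (V[j + 1] == 0.0 && A < 0.0) coef_j1 += A * del;
      // F_{j+1/2} appears with -dt/Delta_j in row j and +dt/Delta_{j+1} in row j+1
      b[j]     += dt / Delta[j] * coef_j;
      c[j]     += dt / Delta[j] * coef_j1;
      a[j + 1] -= dt / Delta[j + 1] * coef_j;
      b[j + 1] -= dt / Delta[j + 1] * coef_j1;
    }
    for (int j = 0; j < G; ++j)
      r[j] = along_x ? phi(j, k) : phi(k, j);
    // Thomas algorithm
    cp[0] = c[0] / b[0]; dp[0] = r[0] / b[0];
    for (int j = 1; j < G; ++j) {
      double m = b[j] - a[j] * cp[j - 1];
      cp[j] = c[j] / m;
      dp[j] = (r[j] - a[j] * dp[j - 1]) / m;
    }
    r[G - 1] = dp[G - 1];
    for (int j = G - 2; j >= 0; --j) r[j] = dp[j] - cp[j] * r[j + 1];
    for (int j = 0; j < G; ++j) {
      double v = r[j] > 0.0 ? r[j] : 0.0;
      if (along_x) phi(j, k) = v; else phi(k, j) = v;
    }
  }
}

// Integrate phi forward for duration T with symmetric scaled migration 'mig'
// (units 2*N_ref*m) and theta0 influx of new mutations on each axis.
// [[Rcpp::export]]
NumericMatrix phi_integrate_cpp(NumericMatrix phi_in, NumericVector xx_in,
                                double T, double nu1, double nu2,
                                double mig, double theta0, double dt0) {
  NumericMatrix phi = clone(phi_in);
  int G = xx_in.size();
  std::vector<double> xx(xx_in.begin(), xx_in.end());
  if (T <= 0.0) return phi;
  int nstep = (int)std::ceil(T / dt0);
  double dt = T / nstep;
  double dx1 = xx[1] - xx[0], dx2 = xx[2] - xx[0];
  double d1 = dx2 / 2.0;                 // trapezoid cell width at node 1
  double d0 = dx1 / 2.0;                 // cell width at the boundary node
  for (int s = 0; s < nstep; ++s) {
    // new mutations enter each population at frequency ~0 in that population
    phi(1, 0) += dt * theta0 / 2.0 / xx[1] / (d1 * d0);
    phi(0, 1) += dt * theta0 / 2.0 / xx[1] / (d1 * d0);
    sweep(phi, xx, nu1, mig, dt, true);
    sweep(phi, xx, nu2, mig, dt, false);
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return phi;
}

// Trapezoid-sample phi onto the (n1+1) x (n2+1) expected spectrum.
// [[Rcpp::export]]
NumericMatrix phi_to_spectrum_cpp(NumericMatrix phi, NumericVector xx,
                                  int n1, int n2) {
  int G = xx.size();
  std::vector<double> w(G);
  w[0] = (xx[1] - xx[0]) / 2.0; w[G - 1] = (xx[G - 1] - xx[G - 2]) / 2.0;
  for (int j = 1; j < G - 1; ++j) w[j] = (xx[j + 1] - xx[j - 1]) / 2.0;
  // binomial kernels
  NumericMatrix K1(n1 + 1, G), K2(n2 + 1, G);
  for (int j = 0; j < G; ++j) {
    for (int i = 0; i <= n1; ++i) K1(i, j) = R::dbinom(i, n1, xx[j], 0);
    for (int i = 0; i <= n2; ++i) K2(i, j) = R::dbinom(i, n2, xx[j], 0);
  }
  NumericMatrix S(n1 + 1, n2 + 1);
  for (int i = 0; i <= n1; ++i)
    for (int jj = 0; jj <= n2; ++jj) {
      double acc = 0.0;
      for (int p = 0; p < G; ++p) {
        double kx = K1(i, p) * w[p];
        if (kx == 0.0) continue;
        double inner = 0.0;
        for (int q = 0; q < G; ++q) inner += K2(jj, q) * w[q] * phi(p, q);
        acc += kx * inner;
      }
      S(i, jj) = acc;
    }
  return S;
}
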