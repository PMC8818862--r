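// Trajectory integrator for the pump-leak model.
//
// Contents q = (qNa, qK, qCl) per mmol A are advanced in time; at every
// derivative evaluation the water volume follows from osmotic balance,
//   v = (qNa + qK + qCl + 1000*a) / osm_ext,
// and the dimensionless membrane potential u is re-solved from the
// zero-net-charge-flux condition (channels + pump; cotransporters are
// electroneutral).  Charge conservation then makes qNa + qK - qCl an exact
// invariant of the motion, up to the root-solve tolerance.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Pars {
  double pna, pk, pcl, beta, gamma, inc, ikc, inkcc, kb;
};

// u/(1 - e^u); 3-term series at the removable singularity u = 0
static inline double u_over_g(double u) {
  if (std::fabs(u) < 1e-4)
    return -1.0 / (1.0 + u / 2.0 + u * u / 6.0 + u * u * u / 24.0);
  return u / (1.0 - std::exp(u));
}

// net charge flux through channels + pump at potential u
static inline double charge_flux(double u, double na, double k, double cl,
                                 const double *med, const Pars &p,
                                 double beta_t) {
  double w = u_over_g(u), eu = std::exp(u);
  double jna = p.pna * w * (na * eu - med[0]);
  double jk  = p.pk  * w * (k  * eu - med[1]);
  double jcl = p.pcl * w * (cl - med[2] * eu);
  return jna + jk - jcl - beta_t * na * (1.0 - 1.0 / p.gamma);
}

// bisection root of charge_flux over u in [-10, 5] (widened once if needed)
static double solve_u(double na, double k, double cl, const double *med,
                      const Pars &p, double beta_t) {
  double lo = -10.0, hi = 5.0;
  double flo = charge_flux(lo, na, k, cl, med, p, beta_t);
  double fhi = charge_flux(hi, na, k, cl, med, p, beta_t);
  if (flo * fhi > 0.0) {
    lo = -25.0; hi = 20.0;
    flo = charge_flux(lo, na, k, cl, med, p, beta_t);
    fhi = charge_flux(hi, na, k, cl, med, p, beta_t);
    if (flo * fhi > 0.0)
      stop("zero-current solve failed: no sign change over u in [-25, 20]");
  }
  for (int it = 0; it < 200 && (hi - lo) > 1e-14; ++it) {
    double mid = 0.5 * (lo + hi);
    double fm = charge_flux(mid, na, k, cl, med, p, beta_t);
    if (fm == 0.0) return mid;
    if (flo * fm < 0.0) { hi = mid; fhi = fm; } else { lo = mid; flo = fm; }
  }
  return 0.5 * (lo + hi);
}

// content derivatives dq/dt at contents q; also reports v and u
static void derivs(const double *q, double z, double a, const double *med,
                   const Pars &p, double beta_t, double *dq,
                   double *v_out, double *u_out) {
  double osm = med[0] + med[1] + med[2] + med[3];
  double v = (q[0] + q[1] + q[2] + 1000.0 * a) / osm;
  double na = q[0] / v, k = q[1] / v, cl = q[2] / v;
  double u = solve_u(na, k, cl, med, p, beta_t);
  double w = u_over_g(u), eu = std::exp(u);
  double jna = p.pna * w * (na * eu - med[0]);
  double jk  = p.pk  * w * (k  * eu - med[1]);
  double jcl = p.pcl * w * (cl - med[2] * eu);
  double jnc   = p.inc   * (med[0] * med[2] - na * cl);
  double jkc   = p.ikc   * (med[1] * med[2] - k * cl);
  double jnkcc = p.inkcc * (med[0] * med[1] * med[2] * med[2] -
                            na * k * cl * cl);
  dq[0] = v * (jna - beta_t * na + jnc + jnkcc);
  dq[1] = v * (jk + beta_t * na / p.gamma + jkc + jnkcc);
  dq[2] = v * (jcl + jnc + jkc + 2.0 * jnkcc);
  *v_out = v;
  *u_out = u;
}

// [[Rcpp::export(name = ".pl_integrate_cpp")]]
List pl_integrate_cpp(NumericVector q0, double z, double a,
                      NumericVector pars, NumericVector med_in,
                      double duration, double dt, int record_every,
                      double stop_tol, double t0, int scheme) {
  if (q0.size() != 3) stop("q0 must have length 3");
  if (pars.size() != 9) stop("pars must have length 9");
  if (med_in.size() != 4) stop("medium must have length 4");
  if (dt <= 0.0 || duration < 0.0) stop("need dt > 0 and duration >= 0");
  Pars p = {pars[0], pars[1], pars[2], pars[3], pars[4],
            pars[5], pars[6], pars[7], pars[8]};
  double med[4] = {med_in[0], med_in[1], med_in[2], med_in[3]};
  long nsteps = (long)std::floor(duration / dt + 0.5);
  if (record_every < 1) record_every = 1;

  std::vector<double> rt, rq1, rq2, rq3, rv, ru;
  double q[3] = {q0[0], q0[1], q0[2]};
  double dq[3], v, u, k1[3], k2[3], k3[3], k4[3], qs[3];
  bool converged = false;
  long i = 0;

  for (i = 0; i <= nsteps; ++i) {
    double t = i * dt;
    double beta_t = std::max(0.0, p.beta * (1.0 - p.kb * (t0 + t)));
    if (i % record_every == 0 || i == nsteps || converged) {
      derivs(q, z, a, med, p, beta_t, dq, &v, &u);
      rt.push_back(t); rq1.push_back(q[0]); rq2.push_back(q[1]);
      rq3.push_back(q[2]); rv.push_back(v); ru.push_back(u);
    }
    if (i == nsteps || converged) break;
    if (scheme == 0) {  // explicit Euler
      derivs(q, z, a, med, p, beta_t, dq, &v, &u);
      for (int j = 0; j < 3; ++j) q[j] += dt * dq[j];
    } else {            // classical RK4 (beta held over the step)
      derivs(q, z, a, med, p, beta_t, k1, &v, &u);
      for (int j = 0; j < 3; ++j) qs[j] = q[j] + 0.5 * dt * k1[j];
      derivs(qs, z, a, med, p, beta_t, k2, &v, &u);
      for (int j = 0; j < 3; ++j) qs[j] = q[j] + 0.5 * dt * k2[j];
      derivs(qs, z, a, med, p, beta_t, k3, &v, &u);
      for (int j = 0; j < 3; ++j) qs[j] = q[j] + dt * k3[j];
      derivs(qs, z, a, med, p, beta_t, k4, &v, &u);
      for (int j = 0; j < 3; ++j)
        q[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      dq[0] = k1[0]; dq[1] = k1[1]; dq[2] = k1[2];
    }
    for (int j = 0; j < 3; ++j)
      if (!std::isfinite(q[j]) || q[j] < 0.0)
        stop("integration failed at t = %g min: non-finite or negative content",
             (i + 1) * dt);
    if (stop_tol > 0.0) {  // max relative content change per minute
      double rel = 0.0;
      for (int j = 0; j < 3; ++j) {
        double r = std::fabs(dq[j]) / std::max(q[j], 1e-12);
        if (r > rel) rel = r;
      }
      if (rel < stop_tol) converged = true;  // record once more, then stop
    }
  }
  long n = (long)rt.size();
  return List::create(
    _["t"] = NumericVector(rt.begin(), rt.end()),
    _["qna"] = NumericVector(rq1.begin(), rq1.end()),
    _["qk"] = NumericVector(rq2.begin(), rq2.end()),
    _["qcl"] = NumericVector(rq3.begin(), rq3.end()),
    _["v"] = NumericVector(rv.begin(), rv.end()),
    _["u"] = NumericVector(ru.begin(), ru.end()),
    _["converged"] = converged,
    _["t_end"] = n > 0 ? rt[n - 1] : 0.0);
}
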