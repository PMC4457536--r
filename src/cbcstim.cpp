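#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Frozen unit system: mV, ms, uA/cm2, mS/cm2, uM, um, kOhm, uF.
// RT/2F at 25 C (298.15 K), F = 96489 C/mol as used throughout the model.
static const double FARADAY = 96489.0;
static const double RT2F_MV = 1000.0 * 8.314462618 * 298.15 / (2.0 * FARADAY);
// d[Ca]/dt [uM/ms] = -CAFLUX * (s/v)[1/um] * i[uA/cm2] / (2F) - ([Ca]-[Ca]res)/tau
static const double CAFLUX = 1.0e4;

struct Gate { double minf, taum, hinf, tauh; };

// T-type kinetics: one activating, one inactivating gate.
static inline Gate t_gate(double vm) {
  Gate g;
  g.minf = 1.0 / (1.0 + std::exp(-(vm - 37.55) / 3.07));
  g.taum = 1.36 + 21.68 / (1.0 + std::exp((vm - 39.96) / 4.11));
  g.hinf = 1.0 / (1.0 + std::exp((vm - 8.97) / 8.42));
  g.tauh = 65.82 + 0.0023 * std::exp((vm - 80.0) / 4.78);
  return g;
}

// L-type kinetics: rate-form activation (removable singularity at vm = 63),
// sigmoid inactivation with fixed 292 ms time constant.
static inline Gate l_gate(double vm) {
  Gate g;
  double x = vm - 63.0;
  double am;
  if (std::fabs(x) < 1e-6) am = 0.427 * 10.5;
  else am = 0.427 * x / (1.0 - std::exp(-x / 10.5));
  double bm = 0.0406 * std::exp((70.0 - vm) / 12.0);
  double s = am + bm;
  g.minf = (std::isfinite(s) && s > 0.0) ? am / s : (am > bm ? 1.0 : 0.0);
  g.taum = (std::isfinite(s) && s > 0.0) ? 1.0 / s : 0.0;
  g.hinf = 1.0 / (1.0 + std::exp(vm / 66.4));
  g.tauh = 292.0;
  return g;
}

static inline double gate_relax(double x, double xinf, double tau, double dt) {
  if (!(tau > 0.0)) return xinf;
  double y = xinf + (x - xinf) * std::exp(-dt / tau);
  if (y < 0.0) y = 0.0;
  if (y > 1.0) y = 1.0;
  return y;
}

static inline double eff_reversal(double cai, double cao, double w, double ek) {
  return w * RT2F_MV * std::log(cao / cai) + (1.0 - w) * ek;
}

// Exact exponential relaxation of Eq.-11-style calcium toward the fixed point
// implied by a current held constant over the step.
static inline double ca_relax(double ca, double ica, double sv, double ca_res,
                              double tau, double dt) {
  double J = CAFLUX * sv * ica / (2.0 * FARADAY); // uM/ms, outward positive
  double target = ca_res - tau * J;
  double y = target + (ca - target) * std::exp(-dt / tau);
  // [Ca]_res is the minimal residual level: outward (K+-carried) current
  // cannot deplete the pool below it
  return (y < ca_res) ? ca_res : y;
}

// Multi-compartment cable integrator.
//
// parent: 0-based parent index per compartment, -1 for the root; every
//   non-root must have parent index smaller than its own (Hines ordering).
// g_par: axial conductance (1/kOhm) of the edge to the parent, 0 at root.
// chan:  0 = passive, 1 = T-type, 2 = L-type on that compartment.
// ve_profile: extracellular potential (mV) per compartment for a unit drive;
//   the waveform vector scales it per step (value at the end of the step).
// Backward-Euler solve for the voltage coupling (channel conductance
// linearised at the freshly updated gates), exact exponential gate and
// calcium updates.
// [[Rcpp::export]]
List cable_run_cpp(IntegerVector parent, NumericVector g_par,
                   NumericVector cap, NumericVector gleak_abs,
                   IntegerVector chan, NumericVector gch_max_abs,
                   NumericVector gbar_dens, NumericVector sv,
                   double wmix_t, double wmix_l, double ek,
                   double ca_res, double ca_tau, double ca_o,
                   NumericVector ve_profile, NumericVector wave,
                   NumericVector i_inj, double vrest, double eleak,
                   double dt, int stride, NumericVector v0,
                   NumericVector m0, NumericVector h0, NumericVector ca0,
                   double blowup) {
  const int n = parent.size();
  const int nt = wave.size();
  const int nrec = nt / stride + 1;

  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> m(m0.begin(), m0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> ca(ca0.begin(), ca0.end());
  std::vector<double> d(n), rhs(n), gch(n), eeff(n), ica(n, 0.0);

  NumericMatrix Vrec(nrec, n), Carec(nrec, n), Irec(nrec, n);
  NumericVector trec(nrec);
  int irec = 0;
  for (int i = 0; i < n; ++i) {
    Vrec(0, i) = V[i] + vrest;
    Carec(0, i) = ca[i];
    Irec(0, i) = 0.0;
  }
  trec[0] = 0.0;

  for (int it = 0; it < nt; ++it) {
    double w = wave[it];
    // gates + channel conductances at start-of-step voltage
    for (int i = 0; i < n; ++i) {
      if (chan[i] == 0) { gch[i] = 0.0; continue; }
      double vm = V[i] + vrest;
      Gate g = (chan[i] == 1) ? t_gate(vm) : l_gate(vm);
      m[i] = gate_relax(m[i], g.minf, g.taum, dt);
      h[i] = gate_relax(h[i], g.hinf, g.tauh, dt);
      double open = (chan[i] == 1) ? m[i] * h[i] : m[i] * m[i] * h[i];
      gch[i] = gch_max_abs[i] * open; // mS (absolute)
      double wm = (chan[i] == 1) ? wmix_t : wmix_l;
      eeff[i] = eff_reversal(ca[i], ca_o, wm, ek);
    }
    // assemble: (C/dt + gl + gch + sum g_axial) V' - offdiag = rhs
    for (int i = 0; i < n; ++i) {
      d[i] = cap[i] / dt + gleak_abs[i] + gch[i];
      rhs[i] = cap[i] / dt * V[i] + gleak_abs[i] * (eleak - vrest) + i_inj[i];
      if (chan[i] != 0) rhs[i] += gch[i] * (eeff[i] - vrest);
    }
    for (int i = 0; i < n; ++i) {
      int p = parent[i];
      if (p < 0) continue;
      double g = g_par[i];
      d[i] += g; d[p] += g;
      double vdrive = g * (ve_profile[p] - ve_profile[i]) * w;
      rhs[i] += vdrive;
      rhs[p] -= vdrive;
    }
    // Hines elimination (children have larger indices than parents)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = g_par[i] / d[i];
      d[p] -= g_par[i] * f;
      rhs[p] += rhs[i] * f;
    }
    V[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      V[i] = (rhs[i] + g_par[i] * V[parent[i]]) / d[i];

    // calcium update from the implicit-step current
    for (int i = 0; i < n; ++i) {
      if (chan[i] == 0) { ica[i] = 0.0; continue; }
      double open = (chan[i] == 1) ? m[i] * h[i] : m[i] * m[i] * h[i];
      ica[i] = gbar_dens[i] * open * (V[i] + vrest - eeff[i]); // uA/cm2
      ca[i] = ca_relax(ca[i], ica[i], sv[i], ca_res, ca_tau, dt);
    }

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > blowup) {
        return List::create(_["ok"] = false, _["t_fail"] = (it + 1) * dt,
                            _["comp"] = i + 1);
      }
    }
    if ((it + 1) % stride == 0) {
      ++irec;
      trec[irec] = (it + 1) * dt;
      for (int i = 0; i < n; ++i) {
        Vrec(irec, i) = V[i] + vrest;
        Carec(irec, i) = ca[i];
        Irec(irec, i) = ica[i];
      }
    }
  }
  return List::create(_["ok"] = true, _["t"] = trec, _["vm"] = Vrec,
                      _["ca"] = Carec, _["ica"] = Irec,
                      _["m"] = NumericVector(m.begin(), m.end()),
                      _["h"] = NumericVector(h.begin(), h.end()));
}

// Single-compartment gating/calcium integration under a commanded membrane
// voltage trace (voltage clamp); returns current density and state traces.
// [[Rcpp::export]]
List clamp_run_cpp(int type, double gbar, double wmix, double ek,
                   NumericVector vm, double dt, double sv,
                   double ca_res, double ca_tau, double ca_o,
                   bool dynamic_ca, int stride,
                   double m_init, double h_init, double ca_init) {
  const int nt = vm.size();
  const int nrec = (nt - 1) / stride + 1;
  double m = m_init, h = h_init, ca = ca_init;
  NumericVector trec(nrec), irec(nrec), mrec(nrec), hrec(nrec), carec(nrec);
  int k = 0;
  for (int it = 0; it < nt; ++it) {
    double v = vm[it];
    if (it > 0) {
      Gate g = (type == 1) ? t_gate(v) : l_gate(v);
      m = gate_relax(m, g.minf, g.taum, dt);
      h = gate_relax(h, g.hinf, g.tauh, dt);
    }
    double open = (type == 1) ? m * h : m * m * h;
    double e = eff_reversal(ca, ca_o, wmix, ek);
    double cur = gbar * open * (v - e);
    if (it > 0 && dynamic_ca) ca = ca_relax(ca, cur, sv, ca_res, ca_tau, dt);
    if (it % stride == 0) {
      trec[k] = it * dt; irec[k] = cur; mrec[k] = m; hrec[k] = h; carec[k] = ca;
      ++k;
    }
  }
  return List::create(_["t"] = trec, _["i"] = irec, _["m"] = mrec,
                      _["h"] = hrec, _["ca"] = carec);
}

// Mono-compartment membrane (specific capacitance + leak + one Ca channel)
// driven by an injected current density; used by the sinusoidal
// frequency-response harness.
// [[Rcpp::export]]
List mono_cc_cpp(int type, double gbar, double wmix, double ek,
                 NumericVector istim, double dt, double sv,
                 double cm, double gleak, double eleak,
                 double ca_res, double ca_tau, double ca_o, int stride) {
  const int nt = istim.size();
  const int nrec = nt / stride + 1;
  double vmr = eleak;
  Gate g0 = (type == 1) ? t_gate(vmr) : l_gate(vmr);
  double m = g0.minf, h = g0.hinf, ca = ca_res;
  double v = vmr;
  NumericVector trec(nrec), vrec(nrec), irec(nrec), carec(nrec);
  vrec[0] = v; irec[0] = 0.0; carec[0] = ca; trec[0] = 0.0;
  int k = 0;
  for (int it = 0; it < nt; ++it) {
    Gate g = (type == 1) ? t_gate(v) : l_gate(v);
    m = gate_relax(m, g.minf, g.taum, dt);
    h = gate_relax(h, g.hinf, g.tauh, dt);
    double open = (type == 1) ? m * h : m * m * h;
    double gch = gbar * open;
    double e = eff_reversal(ca, ca_o, wmix, ek);
    // implicit in v for leak+channel, explicit drive
    double num = cm / dt * v + gleak * eleak + gch * e + istim[it];
    double den = cm / dt + gleak + gch;
    v = num / den;
    double cur = gch * (v - e);
    ca = ca_relax(ca, cur, sv, ca_res, ca_tau, dt);
    if ((it + 1) % stride == 0) {
      ++k;
      trec[k] = (it + 1) * dt; vrec[k] = v; irec[k] = cur; carec[k] = ca;
    }
  }
  return List::create(_["t"] = trec, _["vm"] = vrec, _["i"] = irec,
                      _["ca"] = carec);
}

// Jacobi-preconditioned conjugate gradients for the 7-point finite-volume
// discretisation of div(sigma grad V) = 0 on a regular grid.
// Gx[i] couples node i and i+1 (x), Gy across one x-row, Gz across one
// xy-plane; a zero edge conductance encodes an insulating (Neumann) face.
// fixed != 0 marks Dirichlet nodes whose value is taken from fixedval.
// [[Rcpp::export]]
List field_cg_cpp(int nx, int ny, int nz,
                  NumericVector Gx, NumericVector Gy, NumericVector Gz,
                  IntegerVector fixed, NumericVector fixedval,
                  double tol, int maxit) {
  const int N = nx * ny * nz;
  const int sx = 1, sy = nx, sz = nx * ny;
  std::vector<double> diag(N, 0.0), b(N, 0.0), x(N, 0.0);
  std::vector<double> r(N, 0.0), z(N, 0.0), p(N, 0.0), Ap(N, 0.0);
  const double *gx = Gx.begin(), *gy = Gy.begin(), *gz = Gz.begin();
  const int *fx = fixed.begin();
  const double *fv = fixedval.begin();

  // diagonal and rhs from Dirichlet elimination
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = i + nx * (j + ny * k);
        if (fx[id]) continue;
        double dsum = 0.0, bs = 0.0;
        if (i + 1 < nx && gx[id] > 0) {
          dsum += gx[id];
          if (fx[id + sx]) bs += gx[id] * fv[id + sx];
        }
        if (i > 0 && gx[id - sx] > 0) {
          dsum += gx[id - sx];
          if (fx[id - sx]) bs += gx[id - sx] * fv[id - sx];
        }
        if (j + 1 < ny && gy[id] > 0) {
          dsum += gy[id];
          if (fx[id + sy]) bs += gy[id] * fv[id + sy];
        }
        if (j > 0 && gy[id - sy] > 0) {
          dsum += gy[id - sy];
          if (fx[id - sy]) bs += gy[id - sy] * fv[id - sy];
        }
        if (k + 1 < nz && gz[id] > 0) {
          dsum += gz[id];
          if (fx[id + sz]) bs += gz[id] * fv[id + sz];
        }
        if (k > 0 && gz[id - sz] > 0) {
          dsum += gz[id - sz];
          if (fx[id - sz]) bs += gz[id - sz] * fv[id - sz];
        }
        diag[id] = dsum;
        b[id] = bs;
      }

  // operator apply on free nodes: (A v)_i = diag_i v_i - sum_free G v_j
  auto apply = [&](const std::vector<double>& v, std::vector<double>& out) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int id = i + nx * (j + ny * k);
          if (fx[id]) { out[id] = 0.0; continue; }
          double acc = diag[id] * v[id];
          if (i + 1 < nx && gx[id] > 0 && !fx[id + sx]) acc -= gx[id] * v[id + sx];
          if (i > 0 && gx[id - sx] > 0 && !fx[id - sx]) acc -= gx[id - sx] * v[id - sx];
          if (j + 1 < ny && gy[id] > 0 && !fx[id + sy]) acc -= gy[id] * v[id + sy];
          if (j > 0 && gy[id - sy] > 0 && !fx[id - sy]) acc -= gy[id - sy] * v[id - sy];
          if (k + 1 < nz && gz[id] > 0 && !fx[id + sz]) acc -= gz[id] * v[id + sz];
          if (k > 0 && gz[id - sz] > 0 && !fx[id - sz]) acc -= gz[id - sz] * v[id - sz];
          out[id] = acc;
        }
  };

  double bnorm = 0.0;
  for (int i = 0; i < N; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  double relres = 0.0;
  int iter = 0;
  if (bnorm > 0.0) {
    for (int i = 0; i < N; ++i) r[i] = b[i]; // x = 0
    double rz = 0.0;
    for (int i = 0; i < N; ++i) {
      if (!fx[i] && diag[i] > 0) z[i] = r[i] / diag[i]; else z[i] = 0.0;
      p[i] = z[i];
      rz += r[i] * z[i];
    }
    for (iter = 1; iter <= maxit; ++iter) {
      apply(p, Ap);
      double pAp = 0.0;
      for (int i = 0; i < N; ++i) pAp += p[i] * Ap[i];
      if (pAp <= 0.0) break;
      double alpha = rz / pAp;
      double rn = 0.0;
      for (int i = 0; i < N; ++i) {
        x[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
        rn += r[i] * r[i];
      }
      relres = std::sqrt(rn) / bnorm;
      if (relres < tol) break;
      double rz_new = 0.0;
      for (int i = 0; i < N; ++i) {
        z[i] = (!fx[i] && diag[i] > 0) ? r[i] / diag[i] : 0.0;
        rz_new += r[i] * z[i];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (int i = 0; i < N; ++i) p[i] = z[i] + beta * p[i];
    }
  }
  NumericVector out(N);
  for (int i = 0; i < N; ++i) out[i] = fx[i] ? fv[i] : x[i];
  return List::create(_["v"] = out, _["iterations"] = iter,
                      _["relres"] = relres);
}
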