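// Semi-implicit time stepping of a multi-compartment neural cable driven by
// extracellular potentials.  Gating variables follow Fohlmeister-Miller-type
// kinetics and are advanced with an exact exponential update at the current
// voltage; the voltage step is backward Euler with channel conductances
// frozen over the step, which reduces to one tridiagonal (Thomas) solve per
// step for the unbranched compartment chain.
//
// Units: mV, ms, mS, uA, uF, mM.  The extracellular potential of compartment
// i at time t is amp_uA * wave[t] * ve_unit[i] (ve_unit in mV/uA); it enters
// through the axial coupling terms, i.e. axial current flows down gradients
// of the intracellular potential Vm + Ve.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double expdec(double u) {
  // u / (exp(u) - 1), continuous at 0
  if (std::fabs(u) < 1e-6) return 1.0 - 0.5 * u;
  return u / (std::exp(u) - 1.0);
}

struct Rates {
  double am, bm, ah, bh, ac, bc, an, bn, aa, ba, aha, bha;
};

static inline Rates fm_rates(double v) {
  Rates r;
  r.am  = 6.0  * expdec(-0.1 * (v + 30.0));
  r.bm  = 20.0 * std::exp(-(v + 55.0) / 18.0);
  r.ah  = 0.4  * std::exp(-(v + 50.0) / 20.0);
  r.bh  = 6.0  / (1.0 + std::exp(-0.1 * (v + 20.0)));
  r.ac  = 3.0  * expdec(-0.1 * (v + 13.0));
  r.bc  = 10.0 * std::exp(-(v + 38.0) / 18.0);
  r.an  = 0.2  * expdec(-0.1 * (v + 40.0));
  r.bn  = 0.4  * std::exp(-(v + 50.0) / 80.0);
  r.aa  = 0.06 * expdec(-0.1 * (v + 90.0));
  r.ba  = 0.1  * std::exp(-(v + 30.0) / 10.0);
  r.aha = 0.04 * std::exp(-(v + 70.0) / 20.0);
  r.bha = 0.6  / (1.0 + std::exp(-0.1 * (v + 40.0)));
  return r;
}

static inline void gate_step(double &x, double a, double b, double dt) {
  double tau = 1.0 / (a + b);
  double xinf = a * tau;
  x = xinf + (x - xinf) * std::exp(-dt / tau);
}

// [[Rcpp::export(name = ".cable_run")]]
List cable_run(List neuron, List state, NumericVector ve_unit,
               NumericVector wave, double amp_uA, double dt,
               double spike_mv, double vmax_mv, bool stop_at_spike,
               bool record_v, int record_every) {
  NumericVector gna = neuron["gna"], gca = neuron["gca"], gk = neuron["gk"],
    ga = neuron["ga"], gkca = neuron["gkca"], gl = neuron["gl"],
    el = neuron["el"], gax = neuron["gax"], cm = neuron["cm"],
    caf = neuron["caf"];
  double ena = neuron["ena"], ek = neuron["ek"], cao = neuron["cao"],
    cares = neuron["cares"], tau_ca = neuron["tau_ca"],
    cadiss = neuron["cadiss"], rtf2 = neuron["rtf2"];

  int n = gna.size();
  int nsteps = wave.size();
  NumericVector v = clone(as<NumericVector>(state["v"]));
  NumericVector m = clone(as<NumericVector>(state["m"]));
  NumericVector hh = clone(as<NumericVector>(state["h"]));
  NumericVector cgate = clone(as<NumericVector>(state["c"]));
  NumericVector ngate = clone(as<NumericVector>(state["n"]));
  NumericVector agate = clone(as<NumericVector>(state["a"]));
  NumericVector hagate = clone(as<NumericVector>(state["ha"]));
  NumericVector ca = clone(as<NumericVector>(state["ca"]));

  std::vector<double> dl(n), dd(n), du(n), rhs(n), ve(n);
  bool spiked = false, unstable = false;
  double spike_time = NA_REAL;
  int spike_comp = NA_INTEGER;

  int nrec = record_v ? (nsteps / record_every + 1) : 0;
  NumericMatrix vtrace(record_v ? n : 0, nrec);
  NumericVector trec(nrec);
  int irec = 0;
  if (record_v) {
    for (int i = 0; i < n; ++i) vtrace(i, 0) = v[i];
    trec[0] = 0.0;
    irec = 1;
  }

  for (int s = 0; s < nsteps && !unstable; ++s) {
    double scale = amp_uA * wave[s];
    for (int i = 0; i < n; ++i) ve[i] = scale * ve_unit[i];

    // gating + calcium at current voltage
    for (int i = 0; i < n; ++i) {
      Rates r = fm_rates(v[i]);
      gate_step(m[i], r.am, r.bm, dt);
      gate_step(hh[i], r.ah, r.bh, dt);
      gate_step(ngate[i], r.an, r.bn, dt);
      if (gca[i] > 0.0 || gkca[i] > 0.0) gate_step(cgate[i], r.ac, r.bc, dt);
      if (ga[i] > 0.0) {
        gate_step(agate[i], r.aa, r.ba, dt);
        gate_step(hagate[i], r.aha, r.bha, dt);
      }
      if (caf[i] > 0.0) {
        double eca = rtf2 * std::log(cao / ca[i]);
        double c3 = cgate[i] * cgate[i] * cgate[i];
        double ica = gca[i] * c3 * (v[i] - eca);
        double dca = -caf[i] * ica - (ca[i] - cares) / tau_ca;
        ca[i] += dt * dca;
        if (ca[i] < 1e-8) ca[i] = 1e-8;
      }
    }

    // assemble tridiagonal backward-Euler system
    for (int i = 0; i < n; ++i) {
      double m3h = m[i] * m[i] * m[i] * hh[i];
      double n4 = ngate[i] * ngate[i]; n4 *= n4;
      double c3 = cgate[i] * cgate[i] * cgate[i];
      double a3ha = agate[i] * agate[i] * agate[i] * hagate[i];
      double gkca_eff = 0.0;
      if (gkca[i] > 0.0) {
        double ratio = ca[i] / cadiss;
        double r2 = ratio * ratio;
        gkca_eff = gkca[i] * r2 / (1.0 + r2);
      }
      double eca = (gca[i] > 0.0) ? rtf2 * std::log(cao / ca[i]) : 0.0;
      double gNa = gna[i] * m3h, gCa = gca[i] * c3, gK = gk[i] * n4,
        gA = ga[i] * a3ha;
      double gsum = gNa + gCa + gK + gA + gkca_eff + gl[i];
      double esum = gNa * ena + gCa * eca + (gK + gA + gkca_eff) * ek +
        gl[i] * el[i];
      dd[i] = cm[i] / dt + gsum;
      rhs[i] = cm[i] / dt * v[i] + esum;
      dl[i] = 0.0; du[i] = 0.0;
      if (i > 0) {
        dl[i] = -gax[i - 1];
        dd[i] += gax[i - 1];
        rhs[i] += gax[i - 1] * (ve[i - 1] - ve[i]);
      }
      if (i < n - 1) {
        du[i] = -gax[i];
        dd[i] += gax[i];
        rhs[i] += gax[i] * (ve[i + 1] - ve[i]);
      }
    }

    // Thomas solve
    for (int i = 1; i < n; ++i) {
      double w = dl[i] / dd[i - 1];
      dd[i] -= w * du[i - 1];
      rhs[i] -= w * rhs[i - 1];
    }
    double vnew_last = rhs[n - 1] / dd[n - 1];
    std::vector<double> vnew(n);
    vnew[n - 1] = vnew_last;
    for (int i = n - 2; i >= 0; --i)
      vnew[i] = (rhs[i] - du[i] * vnew[i + 1]) / dd[i];

    double t_now = (s + 1) * dt;
    for (int i = 0; i < n; ++i) {
      if (!spiked && v[i] < spike_mv && vnew[i] >= spike_mv) {
        spiked = true;
        spike_time = t_now;
        spike_comp = i + 1;
      }
      if (std::fabs(vnew[i]) > vmax_mv) unstable = true;
      v[i] = vnew[i];
    }
    if (record_v && ((s + 1) % record_every == 0) && irec < nrec) {
      for (int i = 0; i < n; ++i) vtrace(i, irec) = v[i];
      trec[irec] = t_now;
      ++irec;
    }
    if (spiked && stop_at_spike) break;
  }

  List out = List::create(
    _["spiked"] = spiked, _["spike_time_ms"] = spike_time,
    _["spike_comp"] = spike_comp, _["unstable"] = unstable,
    _["v"] = v,
    _["state"] = List::create(_["v"] = v, _["m"] = m, _["h"] = hh,
                              _["c"] = cgate, _["n"] = ngate,
                              _["a"] = agate, _["ha"] = hagate,
                              _["ca"] = ca));
  if (record_v) {
    out["vtrace"] = vtrace;
    out["t_ms"] = trec;
    out["n_recorded"] = irec;
  }
  return out;
}
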