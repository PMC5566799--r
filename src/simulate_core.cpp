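#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Conductance-based LIF network integrator.
//
// State per neuron: membrane potential v (mV), refractory countdown, and two
// alpha-conductance stages per synapse type. The alpha kernel
//   g(t) = g_peak * (t/tau) * exp(1 - t/tau)
// is integrated exactly through the two-stage propagator
//   y2(t+dt) = exp(-dt/tau) * (y2 + dt*y1),   y1(t+dt) = exp(-dt/tau) * y1,
// where an incoming spike adds e*g_peak/tau to y1 and y2 is the conductance.
// The voltage uses exponential Euler with conductances frozen over the step.
// Units: pF, nS, mV, ms, pA (consistent: nS*mV = pA, pF*mV/ms = pA).
//
// Recurrent spikes are delivered to targets after `delay` ms as inhibitory
// alpha events through a ring buffer; background Poisson events (rate nu_ext
// per neuron, independent streams off R's RNG) arrive as excitatory alpha
// events. Threshold crossing records a spike at the end of the step, resets
// v and clamps it for t_ref.

// [[Rcpp::export]]
List simulate_core(IntegerMatrix targets, int n_neurons,
                   double C_m, double g_L, double E_L, double V_th,
                   double V_reset, double t_ref, double E_exc, double E_inh,
                   double tau_exc, double tau_inh,
                   double g_peak_exc, double g_peak_inh, double delay,
                   double nu_ext, NumericVector v_init,
                   IntegerVector stim_neuron, NumericVector stim_amp,
                   NumericVector stim_on, NumericVector stim_off,
                   double duration, double dt, int record_neuron) {
  const int n = n_neurons;
  const int k = targets.nrow();
  const bool wired = targets.ncol() == n && k > 0;
  const int nstep = (int)std::ceil(duration / dt);
  const int dsteps = std::max(1, (int)std::lround(delay / dt));
  const int ref_steps = std::max(0, (int)std::lround(t_ref / dt));
  const double lambda = nu_ext * dt / 1000.0; // expected events per step
  const double dec_e = std::exp(-dt / tau_exc);
  const double dec_i = std::exp(-dt / tau_inh);
  const double amp_e = M_E * g_peak_exc / tau_exc;
  const double amp_i = M_E * g_peak_inh / tau_inh;

  std::vector<double> v(v_init.begin(), v_init.end());
  std::vector<double> y1e(n, 0.0), y2e(n, 0.0), y1i(n, 0.0), y2i(n, 0.0);
  std::vector<int> refr(n, 0);
  std::vector<double> ring((size_t)dsteps * n, 0.0);
  std::vector<double> I_ext(n, 0.0);

  // stimulus step events: (step, neuron, delta_I), sorted by step
  struct Ev { int step; int neuron; double dI; };
  std::vector<Ev> events;
  for (int j = 0; j < stim_neuron.size(); ++j) {
    int on = (int)std::lround(stim_on[j] / dt);
    int off = (int)std::lround(stim_off[j] / dt);
    events.push_back({on, stim_neuron[j], stim_amp[j]});
    events.push_back({off, stim_neuron[j], -stim_amp[j]});
  }
  std::sort(events.begin(), events.end(),
            [](const Ev& a, const Ev& b) { return a.step < b.step; });
  size_t ev_ptr = 0;

  std::vector<int> sp_n;
  std::vector<double> sp_t;
  sp_n.reserve(1 << 16);
  sp_t.reserve(1 << 16);
  std::vector<double> vtrace;
  if (record_neuron >= 0) vtrace.reserve(nstep + 1);
  if (record_neuron >= 0) vtrace.push_back(v[record_neuron]);

  for (int s = 0; s < nstep; ++s) {
    // deliver recurrent spikes due this step
    double* slot = &ring[(size_t)(s % dsteps) * n];
    for (int i = 0; i < n; ++i) {
      y1i[i] += slot[i];
      slot[i] = 0.0;
    }
    // background Poisson arrivals
    if (lambda > 0) {
      for (int i = 0; i < n; ++i) {
        double nev = R::rpois(lambda);
        if (nev > 0) y1e[i] += nev * amp_e;
      }
    }
    // stimulus on/off edges
    while (ev_ptr < events.size() && events[ev_ptr].step <= s) {
      I_ext[events[ev_ptr].neuron] += events[ev_ptr].dI;
      ++ev_ptr;
    }
    const double t_spike = (s + 1) * dt;
    for (int i = 0; i < n; ++i) {
      // exact conductance propagation
      y2e[i] = (y2e[i] + dt * y1e[i]) * dec_e;
      y1e[i] *= dec_e;
      y2i[i] = (y2i[i] + dt * y1i[i]) * dec_i;
      y1i[i] *= dec_i;
      if (refr[i] > 0) {
        --refr[i];
        v[i] = V_reset;
        continue;
      }
      const double ge = y2e[i], gi = y2i[i];
      const double g_tot = g_L + ge + gi;
      const double v_inf = (g_L * E_L + ge * E_exc + gi * E_inh + I_ext[i]) / g_tot;
      v[i] = v_inf + (v[i] - v_inf) * std::exp(-dt * g_tot / C_m);
      if (!std::isfinite(v[i]))
        stop("non-finite membrane potential at t = %f ms, neuron %d", t_spike, i);
      if (v[i] >= V_th) {
        sp_n.push_back(i);
        sp_t.push_back(t_spike);
        v[i] = V_reset;
        refr[i] = ref_steps;
        if (wired && amp_i != 0.0) {
          double* out = &ring[(size_t)(s % dsteps) * n];
          const int* tg = &targets(0, i);
          for (int e = 0; e < k; ++e) out[tg[e]] += amp_i;
        }
      }
    }
    if (record_neuron >= 0) vtrace.push_back(v[record_neuron]);
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    Named("neuron") = IntegerVector(sp_n.begin(), sp_n.end()),
    Named("time_ms") = NumericVector(sp_t.begin(), sp_t.end()));
  if (record_neuron >= 0)
    out["v_trace"] = NumericVector(vtrace.begin(), vtrace.end());
  return out;
}
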