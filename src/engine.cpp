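#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven simulation of Izhikevich neurons with exponentially decaying
// current-based synapses and delayed spike delivery over a ring buffer.
//
// Per step (dt):
//   1. external stimulus events emitted this step are scheduled onto their
//      outgoing edges (arrival = emission step + delay_steps),
//   2. arrivals due this step are read off the ring buffer,
//   3. synaptic accumulators decay by exp(-dt/tau) and arrivals are injected,
//   4. every neuron advances one explicit-midpoint RK2 step of
//         dv/dt = 0.04 v^2 + 5 v + 140 - u + I,   du/dt = a (b v - u)
//      with I = g_e - g_i + I_dc held constant over the step,
//   5. neurons with advanced v > 30 spike: recorded v is clamped at 30,
//      v <- c, u <- u + d, and the spike is scheduled onto outgoing edges.
//
// Neuron parameter matrix columns: a, b, c, d, v_init, u_init, i_dc.
// Edge endpoints are 0-based; e_src flags edges whose presynaptic side is an
// external source channel rather than a neuron.  Stimulus events (s_chan,
// s_step) must be sorted by step.  Arrivals falling beyond the simulation end
// are discarded.

// [[Rcpp::export]]
List sim_core(NumericMatrix par, IntegerVector group, int n_groups,
              IntegerVector e_pre, IntegerVector e_post, NumericVector e_w,
              IntegerVector e_delay, IntegerVector e_inh, IntegerVector e_src,
              int n_sources,
              IntegerVector s_chan, IntegerVector s_step,
              double tau_e, double tau_i, double dt, int n_steps,
              bool record_full) {
  const int n = par.nrow();
  const int n_edges = e_pre.size();

  // adjacency (CSR) for neuron-sourced and source-sourced edges
  std::vector<int> ncnt(n + 1, 0), scnt(n_sources + 1, 0);
  for (int e = 0; e < n_edges; ++e) {
    if (e_src[e]) scnt[e_pre[e] + 1]++; else ncnt[e_pre[e] + 1]++;
  }
  for (int i = 0; i < n; ++i) ncnt[i + 1] += ncnt[i];
  for (int i = 0; i < n_sources; ++i) scnt[i + 1] += scnt[i];
  std::vector<int> nadj(ncnt[n]), sadj(scnt[n_sources]);
  {
    std::vector<int> np(ncnt.begin(), ncnt.end() - 1),
                     sp(scnt.begin(), scnt.end() - 1);
    for (int e = 0; e < n_edges; ++e) {
      if (e_src[e]) sadj[sp[e_pre[e]]++] = e; else nadj[np[e_pre[e]]++] = e;
    }
  }

  int max_delay = 1;
  for (int e = 0; e < n_edges; ++e) {
    if (e_delay[e] < 1) stop("edge delay shorter than one time-step");
    if (e_delay[e] > max_delay) max_delay = e_delay[e];
  }
  const int D = max_delay + 1;

  std::vector<double> bufe((size_t)n * D, 0.0), bufi((size_t)n * D, 0.0);
  std::vector<double> v(n), u(n), ge(n, 0.0), gi(n, 0.0);
  std::vector<double> a(n), b(n), cc(n), d(n), idc(n);
  for (int i = 0; i < n; ++i) {
    a[i] = par(i, 0); b[i] = par(i, 1); cc[i] = par(i, 2); d[i] = par(i, 3);
    v[i] = par(i, 4); u[i] = par(i, 5); idc[i] = par(i, 6);
  }
  const double de = std::exp(-dt / tau_e), di = std::exp(-dt / tau_i);

  NumericMatrix vfull = record_full ? NumericMatrix(n, n_steps)
                                    : NumericMatrix(0, 0);
  NumericMatrix vmean(n_groups, n_steps);
  std::vector<int> gsize(n_groups, 0);
  for (int i = 0; i < n; ++i) gsize[group[i]]++;

  std::vector<int> sp_n, sp_t;
  long long delivered = 0;
  R_xlen_t spt = 0;
  const R_xlen_t n_stim = s_step.size();

  for (int t = 0; t < n_steps; ++t) {
    // 1. schedule stimulus emissions of this step
    while (spt < n_stim && s_step[spt] == t) {
      const int ch = s_chan[spt];
      for (int k = scnt[ch]; k < scnt[ch + 1]; ++k) {
        const int e = sadj[k];
        if (t + e_delay[e] < n_steps) {
          const size_t slot = (size_t)e_post[e] * D + (t + e_delay[e]) % D;
          if (e_inh[e]) bufi[slot] += e_w[e]; else bufe[slot] += e_w[e];
          ++delivered;
        }
      }
      ++spt;
    }

    // 2-3. consume arrivals, decay and inject
    const int col = t % D;
    for (int i = 0; i < n; ++i) {
      const size_t slot = (size_t)i * D + col;
      ge[i] = ge[i] * de + bufe[slot]; bufe[slot] = 0.0;
      gi[i] = gi[i] * di + bufi[slot]; bufi[slot] = 0.0;
    }

    // 4-5. advance neurons, detect spikes, record, schedule deliveries
    for (int i = 0; i < n; ++i) {
      const double I = ge[i] - gi[i] + idc[i];
      const double k1v = 0.04 * v[i] * v[i] + 5.0 * v[i] + 140.0 - u[i] + I;
      const double k1u = a[i] * (b[i] * v[i] - u[i]);
      const double vm = v[i] + 0.5 * dt * k1v;
      const double um = u[i] + 0.5 * dt * k1u;
      double vn = v[i] + dt * (0.04 * vm * vm + 5.0 * vm + 140.0 - um + I);
      double un = u[i] + dt * a[i] * (b[i] * vm - um);
      if (!std::isfinite(vn) || !std::isfinite(un))
        stop("integration blow-up in neuron %d at t = %.4f ms", i + 1, t * dt);
      double vrec;
      if (vn > 30.0) {
        vrec = 30.0;
        v[i] = cc[i];
        u[i] = un + d[i];
        sp_n.push_back(i + 1);
        sp_t.push_back(t);
        for (int k = ncnt[i]; k < ncnt[i + 1]; ++k) {
          const int e = nadj[k];
          if (t + e_delay[e] < n_steps) {
            const size_t slot = (size_t)e_post[e] * D + (t + e_delay[e]) % D;
            if (e_inh[e]) bufi[slot] += e_w[e]; else bufe[slot] += e_w[e];
            ++delivered;
          }
        }
      } else {
        vrec = vn;
        v[i] = vn;
        u[i] = un;
      }
      if (record_full) vfull(i, t) = vrec;
      vmean(group[i], t) += vrec;
    }
    if (t % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  for (int g = 0; g < n_groups; ++g)
    if (gsize[g] > 0)
      for (int t = 0; t < n_steps; ++t) vmean(g, t) /= gsize[g];

  return List::create(
    _["v_mean"] = vmean,
    _["v_full"] = record_full ? (SEXP)vfull : R_NilValue,
    _["spike_neuron"] = IntegerVector(sp_n.begin(), sp_n.end()),
    _["spike_step"] = IntegerVector(sp_t.begin(), sp_t.end()),
    _["n_delivered"] = (double)delivered);
}
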