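// Forward-Euler integration of a recurrent AdEx network with
// current-based exponential synapses.
//
// All currents are per membrane capacitance (mV/ms). Synaptic state is
// kept per neuron and per kinetics class (E, I, X filters), decayed
// exactly by exp(-dt/tau) each step; an incoming spike through a
// connection of weight w adds w/tau to the target filter. Recurrent
// spikes are delivered with a one-step delay so the update is
// independent of neuron ordering. During the refractory period the
// membrane is pinned at the reset potential.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".adex_sim")]]
List adex_sim(int NE, int NI,
              NumericVector Vinit,
              List neuron, List kinetics,
              IntegerVector rec_ptr, IntegerVector rec_post, NumericVector rec_w,
              IntegerVector x_ptr, IntegerVector x_post, NumericVector x_w,
              NumericVector ext_times, IntegerVector ext_ids,
              double S, double onset, LogicalVector stim_mask,
              double dt, double duration,
              NumericMatrix epochs,
              IntegerVector record_idx, int record_stride) {
  const int N = NE + NI;
  const double tau_m = neuron["tau_m"], E_L = neuron["E_L"],
    V_T = neuron["V_T"], V_th = neuron["V_th"], Delta_T = neuron["Delta_T"],
    V_re = neuron["V_re"], V_lb = neuron["V_lb"], tau_ref = neuron["tau_ref"],
    tau_w = neuron["tau_w"], B = neuron["B"];
  const double tau_E = kinetics["tau_E"], tau_I = kinetics["tau_I"],
    tau_X = kinetics["tau_X"];
  const double decE = std::exp(-dt / tau_E), decI = std::exp(-dt / tau_I),
    decX = std::exp(-dt / tau_X), decW = std::exp(-dt / tau_w);
  // Cap on the spike-initiation exponent: beyond the hard threshold the
  // crossing test fires anyway, so larger arguments only risk overflow.
  const double argcap = (V_th - V_T) / Delta_T + 5.0;
  const int nsteps = (int)std::lround(duration / dt);
  const int ref_steps = std::max(1, (int)std::lround(tau_ref / dt));

  std::vector<double> V(Vinit.begin(), Vinit.end());
  std::vector<double> w(N, 0.0), sE(N, 0.0), sI(N, 0.0), sX(N, 0.0);
  std::vector<int> refr(N, 0);
  std::vector<int> fired, firing;
  fired.reserve(N); firing.reserve(N);

  std::vector<double> spk_t; std::vector<int> spk_id;
  const int nep = epochs.nrow();
  NumericMatrix sumX(N, nep), sumR(N, nep);
  IntegerMatrix nspk(N, nep);
  std::vector<double> ep_steps(nep, 0.0);

  // map neuron index -> trace column (or -1)
  const int nrec = record_idx.size();
  std::vector<int> rec_col(N, -1);
  for (int c = 0; c < nrec; ++c) rec_col[record_idx[c]] = c;
  const int ntr = (nrec > 0) ? ((nsteps + record_stride - 1) / record_stride) : 0;
  NumericMatrix trX(ntr, nrec), trR(ntr, nrec);
  NumericVector trT(ntr);
  int trrow = 0;

  int ext_pos = 0;
  const int next_spk = ext_times.size();

  for (int n = 0; n < nsteps; ++n) {
    const double t = n * dt;
    // deliver last step's recurrent spikes (one-step delay)
    for (size_t f = 0; f < fired.size(); ++f) {
      const int j = fired[f];
      const bool isE = j < NE;
      const double tau = isE ? tau_E : tau_I;
      for (int e = rec_ptr[j]; e < rec_ptr[j + 1]; ++e) {
        if (isE) sE[rec_post[e]] += rec_w[e] / tau;
        else     sI[rec_post[e]] += rec_w[e] / tau;
      }
    }
    fired.clear();
    // deliver external spikes with times in [t, t + dt)
    while (ext_pos < next_spk && ext_times[ext_pos] < t + dt) {
      const int k = ext_ids[ext_pos];
      for (int e = x_ptr[k]; e < x_ptr[k + 1]; ++e)
        sX[x_post[e]] += x_w[e] / tau_X;
      ++ext_pos;
    }
    const bool stim_on = (S != 0.0) && (t >= onset);
    int ep = -1;
    for (int e = 0; e < nep; ++e)
      if (t >= epochs(e, 0) && t < epochs(e, 1)) { ep = e; break; }
    if (ep >= 0) ep_steps[ep] += 1.0;

    const bool rec_now = (nrec > 0) && (n % record_stride == 0);
    if (rec_now) trT[trrow] = t;

    firing.clear();
    for (int j = 0; j < N; ++j) {
      double Xc = sX[j];
      if (stim_on && j < NE && stim_mask[j]) Xc += S;
      const double Rc = sE[j] + sI[j];
      if (ep >= 0) { sumX(j, ep) += Xc; sumR(j, ep) += Rc; }
      if (rec_now && rec_col[j] >= 0) {
        trX(trrow, rec_col[j]) = Xc;
        trR(trrow, rec_col[j]) = Rc;
      }
      if (refr[j] > 0) {
        --refr[j];
        V[j] = V_re;
      } else {
        double arg = (V[j] - V_T) / Delta_T;
        if (arg > argcap) arg = argcap;
        const double dV = (-(V[j] - E_L) + Delta_T * std::exp(arg)) / tau_m
          + Xc + Rc - w[j];
        V[j] += dt * dV;
        if (V[j] < V_lb) V[j] = V_lb;
        if (V[j] > V_th) {
          spk_t.push_back(t + dt);
          spk_id.push_back(j + 1);
          if (ep >= 0) nspk(j, ep) += 1;
          V[j] = V_re;
          refr[j] = ref_steps;
          w[j] += B;
          firing.push_back(j);
        }
      }
      w[j] *= decW;
      sE[j] *= decE; sI[j] *= decI; sX[j] *= decX;
    }
    if (rec_now) ++trrow;
    std::swap(fired, firing);
  }

  return List::create(
    _["spike_time"] = spk_t, _["spike_id"] = spk_id,
    _["sumX"] = sumX, _["sumR"] = sumR, _["nspike"] = nspk,
    _["epoch_steps"] = NumericVector(ep_steps.begin(), ep_steps.end()),
    _["trX"] = trX, _["trR"] = trR, _["trT"] = trT);
}
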