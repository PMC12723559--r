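// Fixed-step conductance-based LIF network core.
//
// Four synaptic channels per neuron, each a peak-normalized difference of
// exponentials: 0 = AMPA, 1 = NMDA (Jahr-Stewart Mg block), 2 = GABA onto
// the apical compartment class, 3 = GABA onto the basal/somatic class.
// Background drive is an independent excitatory Ornstein-Uhlenbeck
// conductance per neuron. The current-dipole proxy sums pyramidal synaptic
// currents weighted by the signed depth offset of their compartment class.
//
// replay mode freezes the membrane at v_ref and drives the synapses from a
// supplied spike list, making the dipole exactly linear in the synaptic
// weights (open-loop).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Box-Muller normal generator on raw mt19937_64 output; much faster than
// std::normal_distribution with libstdc++'s generate_canonical.
struct FastNormal {
  std::mt19937_64 rng;
  double spare;
  bool has_spare;
  explicit FastNormal(uint64_t seed) : rng(seed), spare(0), has_spare(false) {}
  inline double uniform() {
    // 53-bit mantissa uniform in (0, 1]
    return ((rng() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  inline double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = uniform(), u2 = uniform();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// [[Rcpp::export]]
List sim_core(List neurons, List synapses, List kinetics, List ou,
              List stim, double duration, double dt, double delay,
              double record_dt, int seed, bool replay,
              List replay_spikes, double v_ref) {
  NumericVector C = neurons["C"], gL = neurons["gL"], EL = neurons["EL"],
                Vth = neurons["Vth"], Vreset = neurons["Vreset"],
                tref = neurons["tref"], adapt_b = neurons["adapt_b"];
  const double adapt_tau = as<double>(neurons["adapt_tau"]);
  IntegerVector pop = neurons["pop"]; // 0 = Pyr
  const double z_apical = as<double>(neurons["z_apical"]);
  const double z_basal = as<double>(neurons["z_basal"]);
  const double E_exc = as<double>(neurons["E_exc"]);
  const double E_inh = as<double>(neurons["E_inh"]);
  const double mg = as<double>(neurons["mg"]);
  const int n = C.size();

  IntegerVector ptr = synapses["ptr"], post = synapses["post"],
                chan = synapses["chan"];
  NumericVector w = synapses["w"];

  NumericVector tau_r = kinetics["tau_rise"], tau_d = kinetics["tau_decay"];
  const int nchan = 4;
  std::vector<double> dec_r(nchan), dec_d(nchan), norm(nchan);
  for (int c = 0; c < nchan; ++c) {
    dec_r[c] = std::exp(-dt / tau_r[c]);
    dec_d[c] = std::exp(-dt / tau_d[c]);
    double tp = tau_r[c] * tau_d[c] / (tau_d[c] - tau_r[c]) *
                std::log(tau_d[c] / tau_r[c]);
    norm[c] = 1.0 / (std::exp(-tp / tau_d[c]) - std::exp(-tp / tau_r[c]));
  }

  NumericVector ou_mean = ou["mean"], ou_sd = ou["sd"];
  const double ou_tau = as<double>(ou["tau"]);
  const double ou_a = std::exp(-dt / ou_tau);
  const double ou_b = std::sqrt(1.0 - ou_a * ou_a);

  NumericVector stim_t = stim["time"];
  IntegerVector stim_target = stim["target"], stim_chan = stim["chan"];
  NumericVector stim_w = stim["w"];
  const int nstim = stim_t.size();

  const int nsteps = (int)std::round(duration / dt);
  const int rec_stride = std::max(1, (int)std::round(record_dt / dt));
  const int nrec = nsteps / rec_stride;
  const int dsteps = std::max(1, (int)std::round(delay / dt));

  // per-neuron synaptic states: rise/decay per channel
  std::vector<double> xr(n * nchan, 0.0), xd(n * nchan, 0.0);
  std::vector<double> V(n), refr(n, 0.0), g_ou(n), w_adapt(n, 0.0);
  const double adapt_dec = std::exp(-dt / adapt_tau);
  for (int i = 0; i < n; ++i) {
    V[i] = replay ? v_ref : EL[i];
    g_ou[i] = ou_mean[i];
  }

  // delayed synaptic event ring buffer
  const int ring_n = dsteps + 1;
  std::vector<std::vector<std::pair<int, double> > > ring(ring_n);

  // replay spike schedule (sorted by time on the R side)
  NumericVector rp_t;
  IntegerVector rp_i;
  if (replay) {
    rp_t = as<NumericVector>(replay_spikes["time"]);
    rp_i = as<IntegerVector>(replay_spikes["neuron"]);
  }
  int rp_pos = 0, stim_pos = 0;

  FastNormal rnorm01((uint64_t)seed);

  std::vector<double> spike_time;
  std::vector<int> spike_neuron;
  NumericVector dipole(nrec);
  double rec_acc = 0.0;
  int rec_count = 0, rec_idx = 0;

  const double mgk = mg / 3.57;

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    const int slot = step % ring_n;

    // apply delayed synaptic events due now
    for (size_t k = 0; k < ring[slot].size(); ++k) {
      int idx = ring[slot][k].first;
      double amt = ring[slot][k].second;
      xr[idx] += amt;
      xd[idx] += amt;
    }
    ring[slot].clear();

    // external stimulus events (already delay-resolved)
    while (stim_pos < nstim && stim_t[stim_pos] < t + 0.5 * dt) {
      int idx = stim_target[stim_pos] * nchan + stim_chan[stim_pos];
      xr[idx] += stim_w[stim_pos];
      xd[idx] += stim_w[stim_pos];
      ++stim_pos;
    }

    // replay spikes feed the same connectivity with the same delay
    if (replay) {
      while (rp_pos < rp_t.size() && rp_t[rp_pos] < t + 0.5 * dt) {
        int i = rp_i[rp_pos];
        int target_slot = (step + dsteps) % ring_n;
        for (int e = ptr[i]; e < ptr[i + 1]; ++e)
          ring[target_slot].push_back(
            std::make_pair(post[e] * nchan + chan[e], w[e]));
        ++rp_pos;
      }
    }

    double dip = 0.0;

    for (int i = 0; i < n; ++i) {
      const int base = i * nchan;
      // decay synaptic states
      xr[base + 0] *= dec_r[0]; xd[base + 0] *= dec_d[0];
      xr[base + 1] *= dec_r[1]; xd[base + 1] *= dec_d[1];
      xr[base + 2] *= dec_r[2]; xd[base + 2] *= dec_d[2];
      xr[base + 3] *= dec_r[3]; xd[base + 3] *= dec_d[3];

      const double gA = norm[0] * (xd[base + 0] - xr[base + 0]);
      const double gN = norm[1] * (xd[base + 1] - xr[base + 1]);
      const double gGa = norm[2] * (xd[base + 2] - xr[base + 2]);
      const double gGb = norm[3] * (xd[base + 3] - xr[base + 3]);

      const double v = V[i];
      const double mgblock = 1.0 / (1.0 + mgk * std::exp(-0.062 * v));

      // synaptic currents in pA (nS * mV)
      const double I_ampa = gA * (v - E_exc);
      const double I_nmda = gN * mgblock * (v - E_exc);
      const double I_ga = gGa * (v - E_inh);
      const double I_gb = gGb * (v - E_inh);

      if (pop[i] == 0) {
        // dipole contribution, nA * um
        dip += (I_ga * z_apical + (I_ampa + I_nmda + I_gb) * z_basal) * 1e-3;
      }

      if (!replay) {
        // OU background conductance (exact update, floored when applied)
        g_ou[i] = ou_mean[i] + (g_ou[i] - ou_mean[i]) * ou_a +
                  ou_sd[i] * ou_b * rnorm01();
        const double g_bg = g_ou[i] > 0.0 ? g_ou[i] : 0.0;
        const double I_bg = g_bg * (v - E_exc);

        w_adapt[i] *= adapt_dec; // spike-triggered adaptation current, pA
        if (refr[i] > 0.0) {
          refr[i] -= dt;
          V[i] = Vreset[i];
        } else {
          const double I_total = -gL[i] * (v - EL[i]) - I_ampa - I_nmda -
                                 I_ga - I_gb - I_bg - w_adapt[i];
          V[i] = v + dt * I_total / C[i];
          if (V[i] >= Vth[i]) {
            spike_time.push_back(t + dt);
            spike_neuron.push_back(i);
            V[i] = Vreset[i];
            refr[i] = tref[i];
            w_adapt[i] += adapt_b[i];
            int target_slot = (step + dsteps) % ring_n;
            for (int e = ptr[i]; e < ptr[i + 1]; ++e)
              ring[target_slot].push_back(
                std::make_pair(post[e] * nchan + chan[e], w[e]));
          }
        }
      }
    }

    rec_acc += dip;
    if (++rec_count == rec_stride) {
      if (rec_idx < nrec) dipole[rec_idx++] = rec_acc / rec_stride;
      rec_acc = 0.0;
      rec_count = 0;
    }

    if ((step & 1023) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(V[i]))
          stop("non-finite membrane potential at t = %f ms (neuron %d)",
               t, i + 1);
      }
    }
  }

  return List::create(
    _["spike_time"] = NumericVector(spike_time.begin(), spike_time.end()),
    _["spike_neuron"] = IntegerVector(spike_neuron.begin(),
                                      spike_neuron.end()),
    _["dipole"] = dipole,
    _["fs"] = 1000.0 / (rec_stride * dt)
  );
}
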