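// Simulator for all-to-all networks of quadratic integrate-and-fire neurons
// with double-exponential synapses driven by the population rate:
//   tau dV_i/dt = eta_i + V_i^2 + I(t) + u_ext(t)
// with I = sign * tau * (s2 - s1) and each spike of the source population
// incrementing both s1 and s2 by J/N (the spiking-network realization of
// ds_k/dt = -s_k/tau_k + J r(t)). Spiking uses finite truncation values
// V_peak / V_reset; no compensation for the flight time beyond V_peak.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {
struct Event {
  double t;
  double w;
  bool operator>(const Event& o) const { return t > o.t; }
};
typedef std::priority_queue<Event, std::vector<Event>, std::greater<Event> > EventQueue;

struct QBlock {
  int src, tgt;
  double jump;            // J / N_src per spike
  double tau1, tau2, tau_d;
  double sign;            // +1 excitatory, -1 inhibitory
  double s1, s2, t_state;
  EventQueue q;
  void advance(double t_to) {
    while (!q.empty() && q.top().t <= t_to) {
      Event e = q.top(); q.pop();
      double d = e.t - t_state;
      if (d > 0) { s1 *= std::exp(-d / tau1); s2 *= std::exp(-d / tau2); }
      s1 += e.w; s2 += e.w; t_state = e.t;
    }
    double d = t_to - t_state;
    if (d > 0) { s1 *= std::exp(-d / tau1); s2 *= std::exp(-d / tau2); t_state = t_to; }
  }
  double s() const { return s2 - s1; }
};

struct QPulse { int pop; double t_on, t_off, amp; };
}  // namespace

// [[Rcpp::export]]
List sim_qif_cpp(List pops, List blocks_in, List pulses_in,
                 double t_end, double dt, int record_every,
                 bool record_spikes) {
  int npop = pops.size();
  std::vector<int> n(npop), off(npop);
  std::vector<double> tau(npop), v_peak(npop), v_reset(npop);
  std::vector<std::vector<double> > eta(npop);
  int ntot = 0;
  for (int p = 0; p < npop; ++p) {
    List pp = pops[p];
    n[p] = as<int>(pp["n"]);
    off[p] = ntot; ntot += n[p];
    tau[p] = as<double>(pp["tau"]);
    v_peak[p] = as<double>(pp["v_peak"]);
    v_reset[p] = as<double>(pp["v_reset"]);
    NumericVector e = pp["eta"];
    if ((int)e.size() != n[p]) stop("eta length mismatch");
    eta[p] = std::vector<double>(e.begin(), e.end());
  }
  std::vector<double> V(ntot);
  for (int p = 0; p < npop; ++p) {
    List pp = pops[p];
    NumericVector v0 = pp["v0"];
    for (int i = 0; i < n[p]; ++i) V[off[p] + i] = v0[i % v0.size()];
  }

  int nblk = blocks_in.size();
  std::vector<QBlock> blk(nblk);
  std::vector<std::vector<int> > outgoing(npop);
  for (int b = 0; b < nblk; ++b) {
    List bb = blocks_in[b];
    blk[b].src = as<int>(bb["src"]) - 1;
    blk[b].tgt = as<int>(bb["tgt"]) - 1;
    blk[b].jump = as<double>(bb["jump"]);
    blk[b].tau1 = as<double>(bb["tau1"]);
    blk[b].tau2 = as<double>(bb["tau2"]);
    blk[b].tau_d = as<double>(bb["tau_d"]);
    blk[b].sign = as<double>(bb["sign"]);
    blk[b].s1 = as<double>(bb["s1"]);
    blk[b].s2 = as<double>(bb["s2"]);
    blk[b].t_state = 0.0;
    if (blk[b].src >= 0) outgoing[blk[b].src].push_back(b);
    if (bb.containsElementNamed("jump_times")) {
      NumericVector jt = bb["jump_times"];
      double jw = as<double>(bb["jump_w"]);
      for (int k = 0; k < jt.size(); ++k)
        if (jt[k] >= 0 && jt[k] <= t_end) blk[b].q.push(Event{jt[k], jw});
    }
  }

  std::vector<QPulse> pulses;
  if (pulses_in.size() > 0) {
    NumericVector pp_pop = pulses_in["pop"], pt_on = pulses_in["t_on"],
                  pdur = pulses_in["dur"], pa = pulses_in["amp"];
    for (int k = 0; k < pp_pop.size(); ++k)
      pulses.push_back(QPulse{(int)pp_pop[k] - 1, pt_on[k], pt_on[k] + pdur[k], pa[k]});
  }

  long nsteps = (long)std::llround(t_end / dt);
  long nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec);
  NumericMatrix lfp(nrec, npop);
  NumericMatrix syn(nrec, nblk);
  NumericMatrix rate(nrec, npop);  // spikes per neuron per unit time in the bin

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<int> bin_count(npop, 0);

  for (int p = 0; p < npop; ++p) {
    double m = 0; for (int i = 0; i < n[p]; ++i) m += V[off[p] + i];
    lfp(0, p) = m / n[p];
  }
  for (int b = 0; b < nblk; ++b) syn(0, b) = blk[b].s();

  std::vector<double> cur(npop);
  long irec = 1;
  double bin_dt = record_every * dt;
  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double t_next = t + dt;

    for (int p = 0; p < npop; ++p) cur[p] = 0.0;
    for (int b = 0; b < nblk; ++b)
      cur[blk[b].tgt] += blk[b].sign * tau[blk[b].tgt] * blk[b].s();
    for (size_t k = 0; k < pulses.size(); ++k) {
      double ov = std::min(pulses[k].t_off, t_next) - std::max(pulses[k].t_on, t);
      if (ov > 0) cur[pulses[k].pop] += pulses[k].amp * (ov / dt);
    }

    for (int p = 0; p < npop; ++p) {
      double idt = dt / tau[p];
      for (int i = 0; i < n[p]; ++i) {
        int g = off[p] + i;
        double v_old = V[g];
        double dv = (eta[p][i] + v_old * v_old + cur[p]) * idt;
        double v_new = v_old + dv;
        if (!std::isfinite(v_new)) stop("non-finite voltage at t=%f", t);
        if (v_new >= v_peak[p]) {
          double frac = (v_peak[p] - v_old) / (v_new - v_old);
          if (frac < 0) frac = 0; if (frac > 1) frac = 1;
          double ts = t + frac * dt;
          if (record_spikes) { spike_id.push_back(g + 1); spike_t.push_back(ts); }
          bin_count[p] += 1;
          for (size_t ob = 0; ob < outgoing[p].size(); ++ob) {
            QBlock& B = blk[outgoing[p][ob]];
            B.q.push(Event{ts + B.tau_d, B.jump});
          }
          v_new = v_reset[p];
        }
        V[g] = v_new;
      }
    }

    for (int b = 0; b < nblk; ++b) blk[b].advance(t_next);

    if ((step + 1) % record_every == 0 && irec < nrec) {
      rec_t[irec] = t_next;
      for (int p = 0; p < npop; ++p) {
        double m = 0; for (int i = 0; i < n[p]; ++i) m += V[off[p] + i];
        lfp(irec, p) = m / n[p];
        rate(irec, p) = bin_count[p] / ((double)n[p] * bin_dt);
        bin_count[p] = 0;
      }
      for (int b = 0; b < nblk; ++b) syn(irec, b) = blk[b].s();
      ++irec;
    }
  }

  return List::create(
    _["time"] = rec_t,
    _["lfp"] = lfp,
    _["syn"] = syn,
    _["rate"] = rate,
    _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["v_final"] = NumericVector(V.begin(), V.end()));
}
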