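// Event-handling simulator for all-to-all networks of leaky integrate-and-fire
// neurons with delayed double-exponential conductance synapses.
//
// Voltage equation (per neuron i of a population with time constant tau):
//   tau dV/dt = -(V - V_rest) + sum_b q_b s_b(t) (Vrev_b - V) + u_ext(t) + u_bias_i
// where s_b = A2_b - A1_b is the shared filtered spike train of synapse block b,
// q_b = tau / (tau2_b - tau1_b) the double-exponential normalization, and the
// u terms are currents already divided by their conductances (mV units).
//
// All-to-all blocks share a single synaptic state per block (exact for equal
// weights): every presynaptic spike schedules, after the delay tau_d, a jump of
// size W in both exponentials A1 (rise, tau1) and A2 (decay, tau2).

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

struct Block {
  int src;      // population index, -1 for external
  int tgt;      // population index
  double W;     // per-spike jump (dimensionless)
  double tau1, tau2, tau_d, v_rev;
  double A1, A2;
  double t_state;  // time to which A1/A2 have been advanced
  EventQueue q;

  void advance(double t_to) {
    // pop events up to t_to, decaying exactly between them
    while (!q.empty() && q.top().t <= t_to) {
      Event e = q.top(); q.pop();
      double d = e.t - t_state;
      if (d > 0) {
        A1 *= std::exp(-d / tau1);
        A2 *= std::exp(-d / tau2);
      }
      A1 += e.w;
      A2 += e.w;
      t_state = e.t;
    }
    double d = t_to - t_state;
    if (d > 0) {
      A1 *= std::exp(-d / tau1);
      A2 *= std::exp(-d / tau2);
      t_state = t_to;
    }
  }
  double s() const { return A2 - A1; }
};

struct Pulse {
  int pop;
  double t_on, t_off, u;  // u in mV (current / conductance)
};

}  // namespace

// [[Rcpp::export]]
List sim_if_cpp(List pops, List blocks_in, List pulses_in,
                double t_end, double dt, int record_every,
                bool record_spikes) {
  int npop = pops.size();
  std::vector<int> n(npop), off(npop);
  std::vector<double> tau(npop), v_rest(npop), v_peak(npop), v_reset(npop);
  std::vector<std::vector<double> > ubias(npop);
  int ntot = 0;
  for (int p = 0; p < npop; ++p) {
    List pp = pops[p];
    n[p] = as<int>(pp["n"]);
    off[p] = ntot;
    ntot += n[p];
    tau[p] = as<double>(pp["tau"]);
    v_rest[p] = as<double>(pp["v_rest"]);
    v_peak[p] = as<double>(pp["v_peak"]);
    v_reset[p] = as<double>(pp["v_reset"]);
    NumericVector ub = pp["u_bias"];
    if ((int)ub.size() != n[p]) stop("u_bias length mismatch");
    ubias[p] = std::vector<double>(ub.begin(), ub.end());
  }
  std::vector<double> V(ntot);
  for (int p = 0; p < npop; ++p) {
    List pp = pops[p];
    NumericVector v0 = pp["v0"];
    for (int i = 0; i < n[p]; ++i) V[off[p] + i] = v0[i % v0.size()];
  }

  int nblk = blocks_in.size();
  std::vector<Block> blk(nblk);
  std::vector<std::vector<int> > outgoing(npop);  // blocks fed by each population
  for (int b = 0; b < nblk; ++b) {
    List bb = blocks_in[b];
    blk[b].src = as<int>(bb["src"]) - 1;  // 0 in R means external
    blk[b].tgt = as<int>(bb["tgt"]) - 1;
    blk[b].W = as<double>(bb["W"]);
    blk[b].tau1 = as<double>(bb["tau1"]);
    blk[b].tau2 = as<double>(bb["tau2"]);
    blk[b].tau_d = as<double>(bb["tau_d"]);
    blk[b].v_rev = as<double>(bb["v_rev"]);
    blk[b].A1 = as<double>(bb["A1"]);
    blk[b].A2 = as<double>(bb["A2"]);
    blk[b].t_state = 0.0;
    if (blk[b].tau2 <= blk[b].tau1) stop("tau2 must exceed tau1");
    if (blk[b].src >= 0) outgoing[blk[b].src].push_back(b);
    if (bb.containsElementNamed("jump_times")) {
      NumericVector jt = bb["jump_times"];
      double jw = as<double>(bb["jump_w"]);
      for (int k = 0; k < jt.size(); ++k)
        if (jt[k] >= 0 && jt[k] <= t_end) blk[b].q.push(Event{jt[k], jw});
    }
  }

  std::vector<Pulse> pulses;
  if (pulses_in.size() > 0) {
    NumericVector pp_pop = pulses_in["pop"], pt_on = pulses_in["t_on"],
                  pdur = pulses_in["dur"], pu = pulses_in["u"];
    for (int k = 0; k < pp_pop.size(); ++k)
      pulses.push_back(Pulse{(int)pp_pop[k] - 1, pt_on[k], pt_on[k] + pdur[k], pu[k]});
  }

  long nsteps = (long)std::llround(t_end / dt);
  long nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec);
  NumericMatrix lfp(nrec, npop);
  NumericMatrix syn(nrec, nblk);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  std::vector<int> spike_count(ntot, 0);

  // initial record
  {
    for (int p = 0; p < npop; ++p) {
      double m = 0;
      for (int i = 0; i < n[p]; ++i) m += V[off[p] + i];
      lfp(0, p) = m / n[p];
    }
    for (int b = 0; b < nblk; ++b) syn(0, b) = blk[b].s();
    rec_t[0] = 0.0;
  }

  std::vector<double> coeff(npop), drive(npop);
  long irec = 1;
  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double t_next = t + dt;

    // synaptic coefficients at start of step
    for (int p = 0; p < npop; ++p) { coeff[p] = 0.0; drive[p] = 0.0; }
    for (int b = 0; b < nblk; ++b) {
      int p = blk[b].tgt;
      double q = tau[p] / (blk[b].tau2 - blk[b].tau1);
      double qs = q * blk[b].s();
      coeff[p] += qs;
      drive[p] += qs * blk[b].v_rev;
    }
    // square current pulses (overlap fraction with this step)
    for (size_t k = 0; k < pulses.size(); ++k) {
      double ov = std::min(pulses[k].t_off, t_next) - std::max(pulses[k].t_on, t);
      if (ov > 0) drive[pulses[k].pop] += pulses[k].u * (ov / dt);
    }

    for (int p = 0; p < npop; ++p) {
      double bcoef = 1.0 + coeff[p];
      double efac = std::exp(-bcoef * dt / tau[p]);
      double base = v_rest[p] + drive[p];
      for (int i = 0; i < n[p]; ++i) {
        int g = off[p] + i;
        double vinf = (base + ubias[p][i]) / bcoef;
        double v_old = V[g];
        double v_new = vinf + (v_old - vinf) * efac;
        if (!std::isfinite(v_new)) stop("non-finite voltage at t=%f", t);
        if (v_new >= v_peak[p]) {
          double frac = (v_peak[p] - v_old) / (v_new - v_old);
          if (frac < 0) frac = 0; if (frac > 1) frac = 1;
          double ts = t + frac * dt;
          if (record_spikes) { spike_id.push_back(g + 1); spike_t.push_back(ts); }
          spike_count[g] += 1;
          for (size_t ob = 0; ob < outgoing[p].size(); ++ob) {
            Block& B = blk[outgoing[p][ob]];
            B.q.push(Event{ts + B.tau_d, B.W});
          }
          v_new = v_reset[p];
        }
        V[g] = v_new;
      }
    }

    // advance synaptic states to end of step (processes due events exactly)
    for (int b = 0; b < nblk; ++b) blk[b].advance(t_next);

    if ((step + 1) % record_every == 0 && irec < nrec) {
      rec_t[irec] = t_next;
      for (int p = 0; p < npop; ++p) {
        double m = 0;
        for (int i = 0; i < n[p]; ++i) m += V[off[p] + i];
        lfp(irec, p) = m / n[p];
      }
      for (int b = 0; b < nblk; ++b) syn(irec, b) = blk[b].s();
      ++irec;
    }
  }

  return List::create(
    _["time"] = rec_t,
    _["lfp"] = lfp,
    _["syn"] = syn,
    _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["spike_count"] = IntegerVector(spike_count.begin(), spike_count.end()),
    _["v_final"] = NumericVector(V.begin(), V.end()));
}
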