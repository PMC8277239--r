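---
title: "Macroscopic phase response and entrainment of heterogeneous gamma rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macroscopic phase response and entrainment of heterogeneous gamma rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gammaprc)
```

## The scientific question

Gamma-band rhythms (30–100 Hz) generated by mutually inhibitory interneuron
networks (ING) or by the excitatory–inhibitory loop (PING) must adjust their
phase to external input if different rhythms are to synchronize. The
response of the *collective* phase to a brief perturbation — the macroscopic
phase-response curve — can differ qualitatively from the response of the
participating neurons. `gammaprc` provides the simulation and analysis
machinery to demonstrate and quantify one such effect: in networks of
heterogeneously driven integrate-and-fire neurons, a pulse of *inhibition*
that delays every single neuron can *advance* the network rhythm
(a paradoxical, type-II macroscopic PRC), and this paradoxical response
widens the range of frequency detuning over which the rhythm can be
entrained by a periodic "clock" input.

The mechanism is disinhibition: heterogeneity disperses spike times across
the cycle, so a suitably timed external inhibitory pulse delays the lagging
neurons just enough that the within-network inhibition triggered by the
early spikers suppresses their spikes entirely. With fewer spikes, the
within-network inhibition is weaker, every neuron recovers sooner, and the
next volley comes early — an advance caused by inhibition.

## Models

### IF networks

Each neuron obeys a leaky integrate-and-fire equation,

$$\tau \frac{dV_i}{dt} = -(V_i - V_{rest}) + \frac{I^{(syn)}_i}{g_{syn}}
  + \frac{I^{(ext)}_i}{g_{ext}} + \frac{I^{(bias)}_i}{g_{bias}},$$

with threshold/reset at $V_{peak}$/$V_{reset}$. Synapses are delayed
double-exponential conductances: each presynaptic spike increments, after a
delay $\tau_d$, two exponentials $A^{(1)}, A^{(2)}$ (rise $\tau_1$, decay
$\tau_2$), and the current is
$g\,\tau/(\tau_2-\tau_1)\,(A^{(2)}-A^{(1)})(V_{rev}-V_i)$, normalized so
its time integral does not depend on the synaptic time constants. Because
all synapses of a block share one weight and the coupling is all-to-all,
one filtered population spike train per block drives every target — an
exact optimization used by the simulator.

The reference ING network (`ing_network()`) has 500 I-cells
($\tau = 20$ ms, rest −55 mV, threshold −50 mV, reset −60 mV), I–I weight
$3\times10^{-2}$ through 4 nS with $\tau_1 = 0.5$, $\tau_2 = 5$ ms and
$\tau_d = 3$ ms. The reference PING network (`ping_network()`) has 800
E-cells and 200 I-cells with only E→I and I→E blocks. Heterogeneity enters
through the tonic bias current: deterministic Gaussian quantiles
$I_i = I\,(1 + \sqrt2\,CV\,\mathrm{erf}^{-1}(-1+2i/(N+1)))$ for the rhythm
population, and random subthreshold Gaussian drives (mean 3.6 pA,
CV 0.167) for PING I-cells, which stay below threshold without E-input.

### QIF networks and their exact mean-field reduction

Quadratic IF neurons, $\tau \dot V_i = \eta_i + V_i^2 + I(t)$ with
truncation at ±500, receive drives at the quantiles of a Lorentzian
distribution (center $\bar\eta$, half-width $\Delta$). In the limit of
infinitely many neurons the population reduces exactly to two ODEs for the
firing rate $r$ and mean voltage $V$,

$$\tau \dot r = \frac{\Delta}{\pi\tau} + 2 r V, \qquad
  \tau \dot V = V^2 + \bar\eta + I - (\pi\tau r)^2,$$

with $I = -\tau s$ (ING) closing the loop through double-exponential
synaptic filter states driven by the rate.

**Synaptic-kernel normalization.** The package normalizes the mean-field
synapse as $\dot s_{1,2} = -s_{1,2}/\tau_{1,2} + J\,r/(\tau_2-\tau_1)$, so
that each unit of rate injects unit time-integral of drive independent of
the synaptic time constants, matching the IF convention above. This choice
is load-bearing: with $\tau_1 = 0.98$, $\tau_2 = 1$ an *unnormalized*
kernel attenuates the recurrent feedback fifty-fold, and the reference ING
parameter set ($\tau = 10$, $\bar\eta = 20$, $\Delta = 3$, $J = 15$) then
sits at a stable focus instead of the sustained collective oscillation the
analysis requires. With the normalized kernel the same parameters yield a
robust limit cycle (period ≈ 9.85 time units, rate swinging between 0.03
and 0.22) that the 2000-neuron spiking QIF network tracks to within half a
percent in period. The spiking network uses the same convention (per-spike
jump $J/[N(\tau_2-\tau_1)]$).

## Measuring the macroscopic PRC

`measure_fmprc()` measures the finite-amplitude macroscopic PRC (fmPRC) by
direct simulation. The perturbed and unperturbed runs share a bit-identical
trajectory up to the pulse (fixed-step deterministic integration), so the
phase shift is read off by comparing first-spike times of corresponding
volleys, $\Delta\phi_m = (t^{(u)}_m - t^{(p)}_m)/T$, wrapped into
$[-0.5, 0.5)$, positive = advance. Design choices that matter:

* **Readout cycle.** The cycle-wise shift settles after a few cycles; the
  reported `dphi` is the *persistent* shift, read at cycle 5 once two
  consecutive cycles agree within 0.002; the first-cycle shift is kept in
  `dphi_first`. For weak pulses the two coincide.
* **Volley correspondence** is nearest-in-time, which handles strong pulses
  that suppress an entire volley (the shift then winds across the
  $[-0.5,0.5)$ boundary; map construction unwraps it).
* **Phase grid.** 64 uniform phases by default; `refine_jumps` bisects any
  interval whose response jumps by more than the tolerance (down to a
  spacing of 1/1024), which distinguishes steep-but-continuous stretches
  of the fmPRC from true discontinuities.
* **PING averaging** redraws only the I-cell bias realizations (50 by
  default, 500 at full scale); the E-cell quantile vector is fixed.

`single_neuron_prc()` verifies that the microscopic PRC is type I (an
inhibitory pulse only ever delays an isolated neuron), which is what makes
a sign-changing fmPRC paradoxical, and `fmprc_mechanism()` checks the
disinhibition mechanism directly (fewer spikes and weaker within-network
inhibition in the perturbed cycle at advancing phases).

## From PRC to entrainment: the iterated phase map

For a clock of period $T_{clock}$ driving the network with one
conductance-pulse volley per cycle, the phase of the network relative to
the $n$-th clock pulse,
$\Phi_n = (t^{(clock)}_n + \tau_d - t^{(net)}_n)/T_{clock}$, evolves as

$$\Phi_{n+1} = \Phi_n + 1 - \frac{T_{nat}}{T_{clock}}
  \bigl(1 - \Delta\phi(\phi_n)\bigr), \qquad
  \phi_n = \Phi_n T_{clock}/T_{nat} \bmod 1 .$$

`build_map()` tabulates this one-cycle return map from a measured fmPRC;
`fixed_points()` finds diagonal crossings (stable iff $|G'| < 1$);
`iterate_map()` and `bifurcation_diagram()` sweep the detuning
$\Delta f = f_{clock} - f_{nat}$, classifying the attractor (fixed point /
period-$k$ / aperiodic, recurrence tolerance $10^{-4}$ over 4096 kept
iterates with continuation across the sweep). Two geometric descriptors
drive the headline boundaries:

* the *branch structure* of the map drawn on the unit square — branch
  boundaries are the wrap points where $G$ crosses an integer, plus any
  true fmPRC discontinuity;
* whether the attractor's smallest covering arc is confined to the branch
  containing the (possibly unstable) fixed point, or *straddles* a branch
  boundary.

As detuning grows the stable fixed point period-doubles to chaos while the
attractor stays confined near the unstable fixed point; at a slightly
larger detuning the attractor spills across the branch boundary. With the
reference CV = 0.1 network calibrated to 44 Hz and clock volleys of total
weight 0.6, these transitions fall at 7.75 Hz and 7.8 Hz respectively.

**Clock-volley strength.** The clock is modeled as a homogeneous
(CV = 0) ING network whose 500 neurons spike in perfect synchrony, so one
clock volley delivers $N_{clock} \times W^{(ext)}$ through the external
conductance; `clock_train()` + `clock_forcing()` synthesize this train
directly (tested against the simulated homogeneous network). The
per-synapse weight of the reference strong clock is $1.2\times10^{-3}$
(volley total 0.6). This is a deliberate choice between two printed
candidate values that differ by 50×: the alternative ($6\times10^{-2}$ per
synapse, volley total 30) silences the forced network completely beyond
≈4.5 Hz detuning and reduces the fmPRC to a pure reset, which is
incompatible with the entrainment phenomenology this analysis targets
(subharmonic windows, a period-doubling cascade, locking ranges that widen
with heterogeneity); the chosen value reproduces all of it. The map
boundaries shift by roughly 5 Hz per unit of volley weight, so this
normalization is by far the dominant uncertainty in the 7.17/7.28 Hz-scale
boundary values.

## Forced simulations and synchronization typing

`simulate_entrained()` drives the network with the synthesized clock;
`relative_phase_series()` computes $\Phi_n$ cycle by cycle (silent cycles
get the sentinel value 2 and are excluded from the variance);
`classify_sync()` types the state from the LFP spectrum: type 1
($f_{dom} \ne f_{clock}$), type 2 ($f_{dom} = f_{clock}$ with a
subharmonic peak at ≥ 2% of the clock-frequency power), type 3 (no
subharmonic; 1:1 phase synchronization). `phase_diagram()` assembles the
(CV, Δf) diagrams with per-CV recalibration of the mean drive.

## Adjoint imPRC on the reduced system

`find_limit_cycle()` integrates the mean-field ODEs (lsoda, rtol $10^{-8}$)
through a 400-unit transient, measures the period from the inter-peak
intervals of the anchoring synaptic variable ($s_{II}$ for ING, $s_{EI}$
for PING; phase 0 is its peak, since under Lorentzian drives some neurons
spike incessantly and volley onsets are undefined), and samples one period
densely. `adjoint_imprc()` then solves the adjoint equation
$\dot Z = -J^\mathsf{T}(x(t))\,Z$: the monodromy matrix of the variational
equation anchors $Z(0)$ as the left eigenvector at the unit Floquet
multiplier, followed by a single backward pass (stable, because the
remaining multipliers lie inside the unit circle), with the normalization
$\langle Z, F\rangle = 1/T$ enforced pointwise. A plain renormalized
power iteration was rejected: the reference cycle's second multiplier is
0.69, so per-pass convergence is slow and truncating it leaves tens of
percent errors in the voltage component, whereas the monodromy route
matches direct finite-difference phase sensitivities to three digits.

`emft_fmprc()` measures finite-amplitude responses of the reduced system
(square current pulse of height $\Delta V\,\tau/0.02$ over 0.02 time
units, i.e. net deflection $\Delta V$; the instantaneous-increment variant
is what the finite-difference tests use), and `qif_fmprc()` does the same
for the spiking network, averaging the cycle-wise shift over readout
cycles 4–12 to suppress finite-size jitter of the volley times.
`regime_and_response_maps()` labels parameter grids as oscillatory /
stationary / divergent (|V| > $10^4$) and records the maximal paradoxical
component per perturbation scenario.

## What the synthetic inputs do and do not emulate

All inputs are generated in code: deterministic Gaussian/Lorentzian
quantile vectors (bit-identical across calls), seeded Gaussian draws with
negative values rejected and redrawn (negative tonic excitation is outside
the model regime), and periodic pulse trains. The generators emulate the
*static* heterogeneity of the study conditions only — no synaptic noise,
conductance fluctuations, sparse connectivity or plasticity. Passing tests
therefore certify the collective phenomena under static heterogeneity in
all-to-all networks, not robustness to biological noise (the underlying
mechanism is known to carry over to fluctuating heterogeneity, but that is
not exercised here).

## Problem sizes and runtime choices

The package's reference analyses run at "desk scale" by default: 500-neuron
IF networks (the full reference size), 1.5–2.6 s of simulated time per
measurement, 16–64 phase points per fmPRC, 50 PING realizations, 2000
QIF neurons for the spiking-vs-mean-field comparison, and 0.05 Hz detuning
grids for the map sweeps. `run_experiment(scale = "full")` switches the
grid densities and realization counts (never the equations) to
full-fidelity settings. The integration steps are 0.01 ms for IF networks
(halving it moves spike times by well under 0.1 ms), 0.002 time units for
QIF networks, and adaptive lsoda for the mean-field ODEs.

## Known limitations

* The clock-volley normalization discussed above is the main source of
  uncertainty in the absolute detuning boundaries of the map analysis.
* The multi-spike onset along the fixed-40 Hz sweep is sensitive to the
  calibration of the mean drive (the onset interleaves with the bisection
  granularity unless the frequency tolerance is ≤ 0.05 Hz).
* Map predictions assume exactly one clock pulse per network cycle;
  deeply silent regimes (strong forcing, large detuning) violate this and
  are analyzed through the forced simulations instead.
* The mean-field fmPRC at large deflections can eject the trajectory from
  the basin briefly; such phases are flagged missing rather than
  extrapolated.
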