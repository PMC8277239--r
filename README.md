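# gammaprc

Macroscopic phase-response curves and entrainment of gamma rhythms in
heterogeneous spiking networks.

## What this package is for

Interneuron-network (ING) and pyramidal–interneuron (PING) gamma rhythms
respond to external input through the phase response of their *collective*
oscillation. `gammaprc` is a toolkit for computational neuroscientists who
want to measure and analyze that response:

* event-handling simulators (Rcpp) for all-to-all networks of leaky (IF)
  and quadratic (QIF) integrate-and-fire neurons with delayed
  double-exponential conductance synapses and heterogeneous tonic drives;
* the finite-amplitude macroscopic phase-response curve (**fmPRC**),
  measured by comparing volley times of perturbed and unperturbed runs
  that share an identical trajectory up to the pulse;
* the one-clock-cycle iterated phase map built from a measured fmPRC, with
  fixed points, stability, and bifurcation diagrams over the detuning
  between clock and network;
* clock-forced simulations with synchronization typing (frequency
  synchronization, subharmonic response, 1:1 phase locking) and
  (CV, detuning) phase diagrams;
* the exact mean-field reduction of QIF networks with Lorentzian
  heterogeneity (rate–voltage ODEs), its limit cycles, the adjoint-based
  infinitesimal macroscopic PRC (**imPRC**), and finite-amplitude PRCs of
  the reduced system.

The scientific core: with neuronal heterogeneity, the macroscopic PRC of
an ING rhythm becomes type II — a brief *inhibitory* pulse delivered just
after the onset of a spike volley *advances* the rhythm, even though it
delays every individual neuron. The advance arises from disinhibition
(the pulse lets the early spikers' inhibition suppress the laggards'
spikes, weakening the within-network inhibition), and it widens the
detuning range over which a periodic input can entrain the rhythm.

## Worked example

Measure the fmPRC of the reference ING network (500 IF neurons, Gaussian
bias heterogeneity) below and above the paradoxical regime:

```r
library(gammaprc)

# reference network: mean drive 20.4 pA, CV 0.15 -> ~47 Hz rhythm
net <- ing_network(mean_current = 20.4, cv = 0.15, n = 500)
sim <- simulate_network(net, t_end = 2500)
lfp_spectrum(sim$time, sim$lfp[, "I"], transient = 500)$f_dom
#> [1] 47.49881

# hold the frequency at 40 Hz while varying heterogeneity
cal0  <- calibrate_mean_input(function(I) ing_network(I, 0,    500), 40)
cal15 <- calibrate_mean_input(function(I) ing_network(I, 0.15, 500), 40)
round(c(cal0$I, cal15$I), 2)
#> [1] 15.75 10.25

# inhibitory 1600 pA / 0.1 ms probe pulse to every I-cell
pulse <- square_pulse(t_on = NA, amplitude = -1600, duration = 0.1)
prc0  <- measure_fmprc(cal0$net,  pulse, n_phases = 16)
prc15 <- measure_fmprc(cal15$net, pulse, n_phases = 16)

max_advance(prc0)$max        # homogeneous: inhibition only delays
#> [1] -5.098564e-09
max_advance(prc15)$max       # heterogeneous: paradoxical advance
#> [1] 0.1679243
max_advance(prc15)$phase     # ...shortly after volley onset
#> [1] 0.0625
```

The homogeneous network's fmPRC is non-positive at every phase (type I,
pure delay); at CV = 0.15 the same pulse advances the rhythm by up to 17%
of a period when it arrives just after the first spikes of a volley. The
mechanism is visible in `fmprc_mechanism()`: at the advancing phase the
perturbed cycle contains fewer spikes and weaker within-network
inhibition.

On the mean-field side:

```r
lc <- find_limit_cycle(mf_params("ING"))   # tau=10, eta=20, Delta=3, J=15
round(lc$period, 3)
#> [1] 9.853
im <- adjoint_imprc(lc)
range(im$V)                  # sign change: type II imPRC
#> [1] -0.02322236  0.08710270
```

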