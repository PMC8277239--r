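# fmPRC measurement machinery. Networks are kept small; checks about the
# reference configuration live in the acceptance suite.

test_that("zero-amplitude perturbation gives an identically zero fmPRC", {
  net <- tiny_ing(cv = 0.1, n = 100)
  prc <- measure_fmprc(net, square_pulse(NA, 0, 0.1), n_phases = 8)
  expect_true(all(abs(prc$dphi) < 1e-9))
  expect_true(all(abs(prc$dphi_first) < 1e-9))
})

test_that("trajectories are identical before the perturbation arrives", {
  net <- tiny_ing(cv = 0.15, n = 100)
  un <- simulate_network(net, 400)
  pr <- simulate_network(net, 400,
                         pulses = list(square_pulse(200, -1600, 0.1)))
  before <- un$time < 200
  expect_identical(un$lfp[before, ], pr$lfp[before, ])
  expect_identical(un$spikes[un$spikes$t < 200, ],
                   pr$spikes[pr$spikes$t < 200, ])
})

test_that("mid-interval inhibition delays the rhythm (sign convention)", {
  net <- tiny_ing(cv = 0.15, n = 200, mean_current = 15)
  prc <- measure_fmprc(net, square_pulse(NA, -1600, 0.1),
                       phases = c(-0.3, -0.25, -0.2))
  expect_true(all(prc$dphi < 0))
})

test_that("single-neuron PRC matches the piecewise closed form and is type I", {
  I <- 20.4; g_bias <- 0.3; g_ext <- 4; tau <- 20
  v_rest <- -55; v_peak <- -50; v_reset <- -60
  net <- single_if_neuron(I)
  amp <- -1600; d <- 0.1
  prc <- single_neuron_prc(net, square_pulse(NA, amp, d),
                           phases = seq(0.05, 0.9, by = 0.1))
  # inhibitory pulses only ever delay: strictly non-positive shifts
  expect_true(all(prc$dphi <= 1e-9))

  # closed-form crossing-time oracle (linear ODE solved piecewise)
  vinf <- v_rest + I / g_bias
  T0 <- tau * log((vinf - v_reset) / (vinf - v_peak))
  a <- amp / g_ext
  oracle <- vapply(prc$phi, function(ph) {
    tp <- ph * T0
    v_tp <- vinf + (v_reset - vinf) * exp(-tp / tau)
    v_pd <- (vinf + a) + (v_tp - vinf - a) * exp(-d / tau)
    if (v_pd >= v_peak) return(0)
    t_rem <- tau * log((vinf - v_pd) / (vinf - v_peak))
    (T0 - (tp + d + t_rem)) / T0
  }, 0)
  expect_equal(prc$dphi, oracle, tolerance = 0.02)
})

test_that("maximal advance summary flags paradoxical responses", {
  prc <- sine_prc(-0.05)          # strictly delaying on (0, 0.5)
  prc$dphi <- -abs(prc$dphi) - 0.01
  ma <- max_advance(prc)
  expect_false(ma$paradoxical)
  prc2 <- sine_prc(0.05)
  ma2 <- max_advance(prc2)
  expect_true(ma2$paradoxical)
  expect_equal(ma2$max, 0.05, tolerance = 1e-6)
  expect_equal(ma2$max_ms, 0.05 * 25, tolerance = 1e-6)
})

test_that("heterogeneity creates a paradoxical advance in a small ING network", {
  # within-network mechanism: fewer spikes and weaker inhibition in the
  # perturbed cycle at an advancing phase
  net <- tiny_ing(cv = 0.15, n = 200, mean_current = 12)
  prc <- measure_fmprc(net, square_pulse(NA, -1600, 0.1),
                       phases = seq(0, 0.15, by = 0.025))
  ma <- max_advance(prc)
  expect_true(ma$paradoxical)
  mech <- fmprc_mechanism(net, square_pulse(NA, -1600, 0.1), ma$phase)
  expect_lt(mech$spikes_pert, mech$spikes_unpert)
  expect_lt(mech$inh_pert, mech$inh_unpert)
})
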