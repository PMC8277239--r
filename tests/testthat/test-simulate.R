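test_that("uncoupled IF neuron reproduces the closed-form interspike interval", {
  for (I in c(16, 20.4, 28)) {
    sim <- simulate_network(single_if_neuron(I), 60)
    isi <- mean(diff(pop_spikes(sim, "I")$t))
    expect_equal(isi, if_isi_theory(I), tolerance = 0.005)
  }
})

test_that("homogeneous ING network fires in perfectly synchronous volleys", {
  sim <- simulate_network(tiny_ing(cv = 0, n = 60), 500)
  v <- detect_volleys(pop_spikes(sim, "I"), 25, t_min = 150)
  expect_true(all(v$count == 60))
  expect_true(all(v$t_last - v$t_first <= sim$dt))
})

test_that("zero-amplitude pulses leave the trajectory untouched", {
  net <- tiny_ing()
  a <- simulate_network(net, 300)
  b <- simulate_network(net, 300,
                        pulses = list(square_pulse(100, 0, 0.1)))
  expect_identical(a$lfp, b$lfp)
  expect_identical(a$spikes, b$spikes)
})

test_that("shared synaptic state equals the brute-force per-pair sum", {
  net <- tiny_ing(cv = 0.2, n = 10)
  sim <- simulate_network(net, 200)
  sp <- pop_spikes(sim, "I")
  b <- net$connections[[1]]
  # per-target drive: every neuron receives the same shared state, equal to
  # the sum over all presynaptic spikes of W * double-exponential kernels
  brute <- double_exp_waveform(sim$time, sp$t + b$tau_d, b$W, b$tau1, b$tau2)
  expect_equal(sim$syn[, "I->I"], brute, tolerance = 1e-8)
})

test_that("halving the step leaves spike times essentially unchanged", {
  net <- ing_network(20.4, 0.15, 500)
  a <- simulate_network(net, 200, dt = 0.01)
  b <- simulate_network(net, 200, dt = 0.005)
  # volley onsets are the robust observable: single marginal neurons at the
  # suppression boundary may differ between steps without affecting them
  va <- detect_volleys(pop_spikes(a, "I"), 21)
  vb <- detect_volleys(pop_spikes(b, "I"), 21)
  n <- min(nrow(va), nrow(vb))
  expect_gt(n, 6)
  expect_lt(max(abs(va$t_first[1:n] - vb$t_first[1:n])), 0.1)
})

test_that("PING I-cells stay subthreshold without excitatory drive", {
  # E-cells silenced by a subthreshold bias: no spikes anywhere
  net <- ping_network(mean_e = 1, cv_e = 0, n_e = 80, n_i = 20, i_seed = 3)
  sim <- simulate_network(net, 500)
  expect_equal(nrow(pop_spikes(sim, "I")), 0)
  expect_equal(nrow(pop_spikes(sim, "E")), 0)
})

test_that("PING network generates a gamma rhythm carried by the E-I loop", {
  net <- ping_network(mean_e = 5, cv_e = 0.1, n_e = 200, n_i = 50,
                      i_seed = 1, W_e = 1.5e-3 * 4, W_i = 4.5e-3 * 4)
  sim <- simulate_network(net, 1200)
  ve <- detect_volleys(pop_spikes(sim, "E"), 25, t_min = 400)
  vi <- detect_volleys(pop_spikes(sim, "I"), 25, t_min = 400)
  expect_gt(nrow(ve), 10)
  # I volleys follow E volleys within a fraction of a period
  expect_equal(nrow(vi), nrow(ve), tolerance = 2)
  f <- volley_frequency(ve)
  expect_gt(f, 20); expect_lt(f, 80)
})

test_that("QIF spiking network tracks the mean-field limit cycle", {
  net <- qif_ing_network(n = 1000)
  sim <- simulate_network(net, 150, record_spikes = FALSE)
  pk <- gammaprc:::peak_times(sim$time[sim$time > 60],
                              sim$syn[sim$time > 60, 1])
  T_spk <- mean(diff(pk))
  lc <- find_limit_cycle(mf_params("ING"))
  expect_equal(T_spk, lc$period, tolerance = 0.02)
  keep <- sim$time > 60
  # cycle-averaged mean voltage and population rate track the reduction
  expect_equal(mean(sim$lfp[keep, "I"]), mean(lc$states[, "V"]),
               tolerance = 0.3, ignore_attr = TRUE)
  expect_equal(mean(sim$rate[keep, "I"]), mean(lc$states[, "r"]),
               tolerance = 0.1, ignore_attr = TRUE)
})
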